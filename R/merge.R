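# Paired-end merging. Amplicons are short enough that forward and reverse
# reads overlap (often spanning the whole fragment), so merging reduces to
# finding the best gapless alignment between R1 and the reverse complement
# of R2, then taking a quality-weighted consensus.

#' Merge one read pair into an amplicon sequence
#'
#' Slides the reverse-complemented R2 along R1 over every gapless offset,
#' scores each candidate overlap and returns the consensus of the best
#' one. Candidates must have an overlap of at least `min_overlap` and at
#' most `max_overlap` bases, with a mismatch fraction no greater than
#' `max_mismatch_density`. Among admissible candidates the one maximising
#' `matches - 2 * mismatches` wins; ties go to the lower mismatch density,
#' then to the shorter merged sequence, then to the "innie" orientation.
#' When `allow_outies` is `TRUE`, read-through orientations (R2 extending
#' left of R1, as happens when the fragment is shorter than the read
#' length plus adapter) are also considered.
#'
#' At disagreeing overlap positions the base with the higher Phred quality
#' wins (the forward read wins ties); at agreeing positions the consensus
#' quality is the maximum of the two.
#'
#' @param r1,r2 Lists with elements `id`, `seq` (DNA string) and `qual`
#'   (integer Phred scores, one per base). `r2` is in raw sequencing
#'   orientation and is reverse-complemented internally.
#' @param max_overlap Maximum admissible overlap length in bp.
#' @param max_mismatch_density Maximum fraction of mismatching bases in
#'   the overlap.
#' @param allow_outies Consider read-through orientations.
#' @param min_overlap Minimum admissible overlap length in bp.
#' @return A list with `merged` (logical), and when merged: `id`, `seq`,
#'   `qual`, `length`, `overlap`, `mismatches`.
#' @export
#' @examples
#' amp <- "ACGTACGTACGTTTAA"
#' r1 <- list(id = "p", seq = substr(amp, 1, 12), qual = rep(35L, 12))
#' r2 <- list(id = "p", seq = revcomp(substr(amp, 9, 16)), qual = rep(35L, 8))
#' merge_read_pair(r1, r2, min_overlap = 4)$length  # 16
merge_read_pair <- function(r1, r2, max_overlap = 300,
                            max_mismatch_density = 0.5,
                            allow_outies = TRUE, min_overlap = 10) {
  stopifnot(nzchar(r1$seq), nzchar(r2$seq))
  s1 <- strsplit(r1$seq, "")[[1]]
  q1 <- as.integer(r1$qual)
  s2 <- strsplit(revcomp(r2$seq), "")[[1]]  # r2 on the forward strand
  q2 <- rev(as.integer(r2$qual))            # qualities follow the flip
  stopifnot(length(s1) == length(q1), length(s2) == length(q2))
  n1 <- length(s1)
  n2 <- length(s2)

  best <- NULL
  offsets <- seq.int(-(n2 - 1L), n1 - 1L)
  if (!allow_outies) offsets <- offsets[offsets >= 0L]
  for (s in offsets) {
    ov_start <- max(0L, s)              # 0-based, in merged coordinates
    ov_end <- min(n1, s + n2)
    ov <- ov_end - ov_start
    if (ov < min_overlap || ov > max_overlap) next
    i1 <- (ov_start + 1L):ov_end
    i2 <- i1 - s
    mism <- sum(s1[i1] != s2[i2])
    dens <- mism / ov
    if (dens > max_mismatch_density) next
    score <- ov - 3L * mism             # matches - 2 * mismatches
    merged_len <- max(n1, s + n2) - min(0L, s)
    cand <- list(s = s, ov = ov, mism = mism, dens = dens,
                 score = score, merged_len = merged_len)
    if (is.null(best) ||
        cand$score > best$score ||
        (cand$score == best$score && cand$dens < best$dens) ||
        (cand$score == best$score && cand$dens == best$dens &&
         cand$merged_len < best$merged_len) ||
        (cand$score == best$score && cand$dens == best$dens &&
         cand$merged_len == best$merged_len && cand$s > best$s)) {
      best <- cand
    }
  }
  if (is.null(best)) return(list(merged = FALSE, id = r1$id))

  s <- best$s
  lo <- min(0L, s)                      # 0-based merged start
  hi <- max(n1, s + n2)
  len <- hi - lo
  seq_out <- character(len)
  qual_out <- integer(len)
  pos <- (lo + 1L):hi                   # 1-based positions on the r1 axis
  in1 <- pos >= 1L & pos <= n1
  in2 <- pos >= s + 1L & pos <= s + n2
  j <- pos - lo                         # index into output
  # r1-only and r2-only stretches
  only1 <- in1 & !in2
  only2 <- in2 & !in1
  seq_out[j[only1]] <- s1[pos[only1]]
  qual_out[j[only1]] <- q1[pos[only1]]
  seq_out[j[only2]] <- s2[pos[only2] - s]
  qual_out[j[only2]] <- q2[pos[only2] - s]
  # overlap: agreement -> max quality; disagreement -> higher-quality base,
  # forward read winning ties
  both <- in1 & in2
  p1 <- pos[both]
  p2 <- pos[both] - s
  agree <- s1[p1] == s2[p2]
  take1 <- agree | q1[p1] >= q2[p2]
  seq_out[j[both]] <- ifelse(take1, s1[p1], s2[p2])
  qual_out[j[both]] <- ifelse(agree, pmax(q1[p1], q2[p2]),
                              ifelse(take1, q1[p1], q2[p2]))
  list(merged = TRUE, id = r1$id, seq = paste(seq_out, collapse = ""),
       qual = qual_out, length = len, overlap = best$ov,
       mismatches = best$mism)
}

#' Merge paired FASTQ files
#'
#' Reads two pairwise-aligned FASTQ files (optionally gzipped), merges
#' each pair with [merge_read_pair()] and writes the merged reads to a
#' single FASTQ file. Unmergeable pairs are dropped and counted.
#'
#' @param r1_path,r2_path Paths to the forward and reverse FASTQ files.
#' @param out_path Output FASTQ path (`.gz` suffix enables compression);
#'   `NULL` skips writing and returns merged reads in memory.
#' @param ... Passed to [merge_read_pair()].
#' @return A list with `stats` (tibble: `input_pairs`, `merged`,
#'   `merged_fraction`) and `reads` (tibble: `id`, `seq`, `qual` list
#'   column, `length`).
#' @export
merge_fastq <- function(r1_path, r2_path, out_path = NULL, ...) {
  f1 <- read_fastq(r1_path)
  f2 <- read_fastq(r2_path)
  if (nrow(f1) != nrow(f2)) {
    abort_ssr(paste0("paired FASTQ files have different record counts (",
                     nrow(f1), " vs ", nrow(f2), ")"))
  }
  n <- nrow(f1)
  if (n == 0) {
    out <- tibble::tibble(id = character(), seq = character(),
                          qual = list(), length = integer())
  } else {
    # Merging is deterministic per (seq, qual) pair, so merge each distinct
    # pair once and fan the result back out. Amplicon data are highly
    # duplicated, which makes this the main speed lever.
    key <- paste(f1$seq, f2$seq, f1$qual_chr, f2$qual_chr, sep = "\r")
    first <- !duplicated(key)
    uidx <- which(first)
    res <- lapply(uidx, function(i) {
      merge_read_pair(list(id = f1$id[i], seq = f1$seq[i], qual = f1$qual[[i]]),
                      list(id = f2$id[i], seq = f2$seq[i], qual = f2$qual[[i]]),
                      ...)
    })
    take <- match(key, key[first])
    merged_flag <- vapply(res, `[[`, logical(1), "merged")[take]
    keep <- which(merged_flag)
    out <- tibble::tibble(
      id = f1$id[keep],
      seq = vapply(res[take[keep]], `[[`, character(1), "seq"),
      qual = lapply(res[take[keep]], `[[`, "qual"),
      length = vapply(res[take[keep]], `[[`, integer(1), "length")
    )
  }
  stats <- tibble::tibble(
    input_pairs = n,
    merged = nrow(out),
    merged_fraction = ifelse(n == 0, NA_real_, nrow(out) / n)
  )
  if (!is.null(out_path)) write_fastq(out, out_path)
  list(stats = stats, reads = out)
}

# FASTQ I/O via Biostrings; qualities are Phred+33.
read_fastq <- function(path) {
  if (!file.exists(path)) abort_ssr(paste0("FASTQ file not found: ", path))
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  qchr <- as.character(S4Vectors::mcols(x)$qualities)
  quals <- lapply(qchr, function(q) utf8ToInt(q) - 33L)
  tibble::tibble(
    id = names(x) %||% as.character(seq_along(x)),
    seq = as.character(x),
    qual = quals,
    qual_chr = qchr
  )
}

write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$seq)
  names(seqs) <- reads$id
  quals <- Biostrings::BStringSet(vapply(
    reads$qual, function(q) intToUtf8(q + 33L), character(1)
  ))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
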