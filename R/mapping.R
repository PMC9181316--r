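# Anchor index: the last anchor_len bases of each left flank and the first
# anchor_len bases of each right flank. Collisions across loci make reads
# inherently ambiguous, so they are rejected up front.
panel_anchors <- function(panel, anchor_len = 15L) {
  left <- stringr::str_sub(panel$left_flank, -anchor_len)
  right <- stringr::str_sub(panel$right_flank, 1, anchor_len)
  key <- paste(left, right)
  if (anyDuplicated(key)) {
    dup <- panel$locus_id[key %in% key[duplicated(key)]]
    abort(paste0("anchor collision between loci: ",
                 paste(dup, collapse = ", ")),
          class = "strwga_validation_error")
  }
  tibble(locus_id = panel$locus_id, unit = panel$unit,
         left = left, right = right)
}

count_mismatches <- function(a, b) {
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b,
         USE.NAMES = FALSE)
}

# All candidate (read, locus, repeat_count) hits in one orientation.
orientation_hits <- function(x, anchors, read_idx, max_mismatch,
                             max_tract_mismatch) {
  out <- list()
  seqs <- as.character(x)
  for (i in seq_len(nrow(anchors))) {
    lm <- Biostrings::vmatchPattern(anchors$left[i], x,
                                    max.mismatch = max_mismatch)
    rm_ <- Biostrings::vmatchPattern(anchors$right[i], x,
                                     max.mismatch = max_mismatch)
    le <- Biostrings::endIndex(lm)
    rs <- Biostrings::startIndex(rm_)
    cand <- which(lengths(le) > 0 & lengths(rs) > 0)
    if (length(cand) == 0) next
    ul <- nchar(anchors$unit[i])
    for (j in cand) {
      rs_first <- min(rs[[j]])
      lef <- le[[j]][le[[j]] < rs_first]
      if (length(lef) == 0) next
      le_best <- max(lef)
      len <- rs_first - le_best - 1L
      if (len < 0 || len %% ul != 0) next
      r <- len %/% ul
      if (r > 0) {
        tract <- substr(seqs[j], le_best + 1L, rs_first - 1L)
        if (count_mismatches(tract, strrep(anchors$unit[i], r)) >
            max_tract_mismatch) next
      }
      out[[length(out) + 1]] <- tibble(read = read_idx[j],
                                       locus_id = anchors$locus_id[i],
                                       repeat_count = r)
    }
  }
  dplyr::bind_rows(c(list(tibble(read = integer(), locus_id = character(),
                                 repeat_count = integer())), out))
}

#' Assign targeted reads to panel loci by flank-anchored repeat counting
#'
#' A read maps to a locus with repeat count `r` iff both of the locus's
#' flank anchors occur in order, each with at most `max_mismatch`
#' mismatches, the spanned interval is an exact multiple `r` of the unit
#' length, and the interval matches `unit^r` with at most
#' `max_tract_mismatch` mismatches. Reads are tried forward first, then
#' reverse-complemented; a read whose candidate hits span more than one
#' locus (in one orientation, or across the two) is unmapped. Truncated
#' tracts at read ends produce no valid anchor pair and are therefore
#' unmapped — unmapped is a value, not an error.
#'
#' This reproduces alignment against the exhaustive length-permuted
#' reference ([permuted_reference()]) on amplicon reads at a fraction of
#' the cost; the permuted reference remains the defining construction.
#'
#' @param reads Character vector or `Biostrings::DNAStringSet`.
#' @param panel An [str_panel()] tibble.
#' @param anchor_len Anchor length (bp). Default 15.
#' @param max_mismatch Mismatches tolerated per anchor. Default 1.
#' @param max_tract_mismatch Mismatches tolerated in the repeat tract.
#'   Default 1.
#'
#' @return A tibble with one row per read: `read` (index), `locus_id`
#'   (`NA` if unmapped), `repeat_count`.
#' @export
assign_reads <- function(reads, panel, anchor_len = 15L, max_mismatch = 1L,
                         max_tract_mismatch = 1L) {
  x <- if (inherits(reads, "DNAStringSet")) reads
       else Biostrings::DNAStringSet(as.character(reads))
  n <- length(x)
  anchors <- panel_anchors(panel, anchor_len)
  res <- tibble(read = seq_len(n), locus_id = NA_character_,
                repeat_count = NA_integer_)
  if (n == 0) return(res)

  resolve <- function(hits) {
    if (nrow(hits) == 0) return(hits)
    hits %>%
      group_by(.data$read) %>%
      filter(dplyr::n_distinct(.data$locus_id) == 1) %>%
      slice(1) %>%
      ungroup()
  }
  fwd_all <- orientation_hits(x, anchors, seq_len(n), max_mismatch,
                              max_tract_mismatch)
  fwd_amb <- if (nrow(fwd_all) > 0) {
    fwd_all %>% group_by(.data$read) %>%
      filter(dplyr::n_distinct(.data$locus_id) > 1) %>% ungroup() %>%
      distinct(.data$read, .data$locus_id)
  } else fwd_all
  fwd <- resolve(fwd_all)
  todo <- setdiff(seq_len(n), unique(fwd_all$read))
  rev <- tibble(read = integer(), locus_id = character(),
                repeat_count = integer())
  if (length(todo) > 0) {
    rev_all <- orientation_hits(Biostrings::reverseComplement(x[todo]),
                                anchors, todo, max_mismatch,
                                max_tract_mismatch)
    rev <- resolve(rev_all)
  }
  # forward-ambiguous reads stay unmapped even if the reverse pass would
  # hit a different locus
  hits <- dplyr::bind_rows(fwd, rev)
  if (nrow(hits) > 0) {
    res$locus_id[hits$read] <- hits$locus_id
    res$repeat_count[hits$read] <- hits$repeat_count
  }
  res
}

#' Repeat-number histograms from a FASTQ file
#'
#' Maps every read with [assign_reads()] and tallies, per locus, the
#' number of reads observed at each repeat count.
#'
#' @param fastq Path to a FASTQ file (optionally gzip-compressed).
#' @param panel An [str_panel()] tibble.
#' @param cell_id Sample identifier attached to the histograms; defaults
#'   to the FASTQ file name.
#' @inheritParams assign_reads
#'
#' @return A list: `histograms` (tibble `cell_id`, `locus_id`,
#'   `repeat_count`, `reads`, one row per locus/length with at least one
#'   mapped read) and `stats` (list `reads_total`, `reads_mapped`,
#'   `per_locus` tibble).
#' @export
histograms_from_fastq <- function(fastq, panel,
                                  cell_id = sub("\\.(fastq|fq)(\\.gz)?$", "",
                                                basename(fastq)),
                                  anchor_len = 15L, max_mismatch = 1L,
                                  max_tract_mismatch = 1L) {
  if (!file.exists(fastq)) {
    abort(paste0("FASTQ not found: ", fastq), class = "strwga_input_error")
  }
  n_lines <- length(readLines(fastq, n = 4L))
  x <- if (n_lines == 0) {
    Biostrings::DNAStringSet()
  } else {
    tryCatch(Biostrings::readDNAStringSet(fastq, format = "fastq"),
             error = function(e) abort(paste0("unreadable FASTQ: ",
                                              conditionMessage(e)),
                                       class = "strwga_input_error"))
  }
  asg <- assign_reads(x, panel, anchor_len, max_mismatch,
                      max_tract_mismatch)
  mapped <- asg %>% filter(!is.na(.data$locus_id))
  hist <- mapped %>%
    count(.data$locus_id, .data$repeat_count, name = "reads") %>%
    mutate(cell_id = cell_id, .before = 1)
  per_locus <- mapped %>% count(.data$locus_id, name = "reads_mapped")
  list(histograms = hist,
       stats = list(reads_total = length(x), reads_mapped = nrow(mapped),
                    per_locus = per_locus))
}
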