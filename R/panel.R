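#' STR panel objects
#'
#' A panel is a tibble with one row per targeted STR locus and columns
#' `chrom`, `start`, `end` (0-based half-open), `locus_id`, `unit` (repeat
#' unit sequence), `ref_repeats` (reference repeat count), `left_flank` and
#' `right_flank` (flanking sequence extracted from the reference).
#' `str_panel()` validates the invariants and stamps the class.
#'
#' Invariants: `end - start == ref_repeats * nchar(unit)`; `unit` is a
#' primitive repeat (not itself a repetition of a shorter unit); locus ids
#' are unique; no flank carries a run of `unit` long enough to swallow a
#' mapping anchor adjacent to the repeat tract.
#'
#' @param x A data frame with the columns above.
#' @param name Panel name.
#' @param anchor_len Anchor length (bp) used for the flank-run invariant.
#'
#' @return A `str_panel` tibble.
#' @export
str_panel <- function(x, name = "panel", anchor_len = 15L) {
  need <- c("chrom", "start", "end", "locus_id", "unit", "ref_repeats",
            "left_flank", "right_flank")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("panel is missing columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "strwga_input_error")
  }
  x <- as_tibble(x)[need]
  if (nrow(x) == 0) {
    abort("panel must contain at least one locus",
          class = "strwga_input_error")
  }
  if (anyDuplicated(x$locus_id)) {
    abort("panel locus_ids are not unique", class = "strwga_validation_error")
  }
  bad <- x$end - x$start != x$ref_repeats * nchar(x$unit)
  if (any(bad)) {
    abort(paste0("end - start != ref_repeats * unit length at locus ",
                 x$locus_id[which(bad)[1]]),
          class = "strwga_validation_error")
  }
  if (any(x$ref_repeats < 1)) {
    abort(paste0("ref_repeats < 1 at locus ",
                 x$locus_id[which(x$ref_repeats < 1)[1]]),
          class = "strwga_validation_error")
  }
  prim <- vapply(x$unit, unit_is_primitive, logical(1))
  if (any(!prim)) {
    abort(paste0("unit is not a primitive repeat at locus ",
                 x$locus_id[which(!prim)[1]]),
          class = "strwga_validation_error")
  }
  run <- ceiling(anchor_len / nchar(x$unit))
  left_bad <- stringr::str_detect(
    x$left_flank, paste0(vapply(seq_len(nrow(x)),
                                function(i) strrep(x$unit[i], run[i]),
                                character(1)), "$"))
  right_bad <- stringr::str_detect(
    x$right_flank, paste0("^", vapply(seq_len(nrow(x)),
                                      function(i) strrep(x$unit[i], run[i]),
                                      character(1))))
  if (any(left_bad | right_bad)) {
    abort(paste0("flank extends the repeat tract ambiguously at locus ",
                 x$locus_id[which(left_bad | right_bad)[1]]),
          class = "strwga_validation_error")
  }
  structure(x, class = c("str_panel", class(tibble())),
            panel_name = name, anchor_len = as.integer(anchor_len))
}

unit_is_primitive <- function(unit) {
  n <- nchar(unit)
  if (n == 1) return(TRUE)
  for (d in seq_len(n - 1)) {
    if (n %% d == 0 && strrep(substr(unit, 1, d), n / d) == unit) return(FALSE)
  }
  TRUE
}

#' Read an STR panel from a table and a reference genome
#'
#' Reads a 6-column tab-separated locus table (`chrom`, `start`, `end`,
#' `locus_id`, `unit`, `ref_repeats`; `#` comment lines allowed; 0-based
#' half-open coordinates) and extracts `flank_len` bases of flanking
#' sequence on each side of every repeat tract from the reference FASTA.
#'
#' @param table_path Path to the locus table.
#' @param reference_path Path to the reference FASTA.
#' @param flank_len Flank length to extract (bp). Default 40.
#' @param name Panel name; defaults to the table file name.
#'
#' @return A validated [str_panel()] tibble.
#' @export
read_panel <- function(table_path, reference_path, flank_len = 40L,
                       name = basename(table_path)) {
  tab <- readr::read_tsv(table_path, comment = "#", col_names = FALSE,
                         col_types = "ciicci", progress = FALSE)
  if (ncol(tab) != 6) {
    abort("panel table must have 6 columns (chrom, start, end, locus_id, unit, ref_repeats)",
          class = "strwga_input_error")
  }
  names(tab) <- c("chrom", "start", "end", "locus_id", "unit", "ref_repeats")
  tab$locus_id <- as.character(tab$locus_id)
  ref <- Biostrings::readDNAStringSet(reference_path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  missing_chrom <- setdiff(unique(tab$chrom), names(ref))
  if (length(missing_chrom) > 0) {
    abort(paste0("reference lacks chromosome(s): ",
                 paste(missing_chrom, collapse = ", ")),
          class = "strwga_input_error")
  }
  seqs <- as.character(ref)
  lens <- nchar(seqs)[tab$chrom]
  if (any(tab$start - flank_len < 0 | tab$end + flank_len > lens)) {
    bad <- which(tab$start - flank_len < 0 | tab$end + flank_len > lens)[1]
    abort(paste0("coordinates (with ", flank_len, " bp flanks) out of range at locus ",
                 tab$locus_id[bad]),
          class = "strwga_input_error")
  }
  tab$left_flank <- unname(substr(seqs[tab$chrom], tab$start - flank_len + 1,
                                  tab$start))
  tab$right_flank <- unname(substr(seqs[tab$chrom], tab$end + 1,
                                   tab$end + flank_len))
  tract <- unname(substr(seqs[tab$chrom], tab$start + 1, tab$end))
  expect <- vapply(seq_len(nrow(tab)),
                   function(i) strrep(tab$unit[i], tab$ref_repeats[i]),
                   character(1))
  if (any(tract != expect)) {
    abort(paste0("reference tract is not unit x ref_repeats at locus ",
                 tab$locus_id[which(tract != expect)[1]]),
          class = "strwga_validation_error")
  }
  str_panel(tab, name = name)
}

#' Write an STR panel table
#'
#' Writes the 6-column tab-separated locus table read back by
#' [read_panel()]. Flanks are not written; they are re-extracted from the
#' reference on read.
#'
#' @param panel An [str_panel()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  readr::write_tsv(as_tibble(panel)[, c("chrom", "start", "end", "locus_id",
                                        "unit", "ref_repeats")],
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write the reference genome attached to a synthetic panel
#'
#' @param panel A panel produced by [synthetic_panel()] (which carries its
#'   reference sequences) .
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(panel, path) {
  ref <- attr(panel, "reference")
  if (is.null(ref)) {
    abort("panel carries no reference sequences (only synthetic_panel() panels do)",
          class = "strwga_input_error")
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref), path, width = 80)
  invisible(path)
}

#' Generate a synthetic STR panel and matching reference
#'
#' Builds a random targeted STR panel: each locus is a primitive repeat
#' unit drawn from `units` (names are units, values are sampling weights)
#' with a reference repeat count drawn uniformly from `ref_repeats`,
#' embedded in random flanking sequence on synthetic chromosomes. The
#' reference chromosome sequences are attached as the `"reference"`
#' attribute so the panel round-trips through [write_panel()] /
#' [write_reference()] / [read_panel()].
#'
#' @param n_loci Number of loci.
#' @param units Named numeric vector of repeat units and their weights.
#' @param ref_repeats Integer vector of candidate reference repeat counts.
#' @param flank_len Flank length (bp). Default 40.
#' @param loci_per_chrom Loci placed per synthetic chromosome.
#' @param seed Integer seed; the panel is deterministic given it.
#'
#' @return An [str_panel()] tibble with a `"reference"` attribute.
#' @examples
#' p <- synthetic_panel(5, seed = 1)
#' p$locus_id
#' @export
synthetic_panel <- function(n_loci, units = c(AC = 0.9, AGAT = 0.1),
                            ref_repeats = 10:30, flank_len = 40L,
                            loci_per_chrom = 500L, seed = 1L) {
  stopifnot(n_loci >= 1, length(units) >= 1, all(ref_repeats >= 1))
  withr::local_seed(seed)
  unit <- sample(names(units), n_loci, replace = TRUE, prob = units)
  reps <- ref_repeats[sample.int(length(ref_repeats), n_loci,
                                 replace = TRUE)]
  spacer_len <- 20L
  lf <- random_flanks(n_loci, flank_len, unit, side = "left")
  rf <- random_flanks(n_loci, flank_len, unit, side = "right")
  chrom_idx <- ((seq_len(n_loci) - 1) %/% loci_per_chrom) + 1
  chrom <- paste0("chr", chrom_idx)
  piece <- paste0(strrep("T", spacer_len), lf,
                  vapply(seq_len(n_loci),
                         function(i) strrep(unit[i], reps[i]), character(1)),
                  rf)
  start <- integer(n_loci)
  ref_seq <- character(0)
  for (ci in unique(chrom_idx)) {
    idx <- which(chrom_idx == ci)
    offs <- cumsum(c(0, head(nchar(piece[idx]), -1)))
    start[idx] <- offs + spacer_len + flank_len
    ref_seq[paste0("chr", ci)] <- paste0(paste(piece[idx], collapse = ""),
                                         strrep("T", spacer_len))
  }
  tab <- tibble(chrom = chrom, start = as.integer(start),
                end = as.integer(start + reps * nchar(unit)),
                locus_id = sprintf("L%05d", seq_len(n_loci)),
                unit = unit, ref_repeats = reps,
                left_flank = lf, right_flank = rf)
  p <- str_panel(tab, name = sprintf("synthetic-%d", n_loci))
  attr(p, "reference") <- ref_seq
  p
}

# Random flanking sequence that never ends (left side) or starts (right
# side) with a full copy of the locus unit, keeping the repeat boundary
# unambiguous.
random_flanks <- function(n, flank_len, unit, side) {
  bases <- c("A", "C", "G", "T")
  mat <- matrix(sample(bases, n * flank_len, replace = TRUE), nrow = n)
  fl <- apply(mat, 1, paste, collapse = "")
  for (i in seq_len(n)) {
    if (side == "left") {
      while (endsWith(fl[i], unit[i])) {
        k <- nchar(fl[i])
        bad <- substr(fl[i], k, k)
        substr(fl[i], k, k) <- sample(setdiff(bases, bad), 1)
      }
    } else {
      while (startsWith(fl[i], unit[i])) {
        bad <- substr(fl[i], 1, 1)
        substr(fl[i], 1, 1) <- sample(setdiff(bases, bad), 1)
      }
    }
  }
  fl
}

#' Length-permuted mapping reference
#'
#' For every panel locus, emits one record per repeat count `r` in the
#' permutation range, with sequence `left_flank + unit^r + right_flank` and
#' record id `"locus_id|r"`. This is the exhaustive reference an STR-aware
#' aligner maps against; [assign_reads()] reproduces its result with
#' flank-anchored counting at a fraction of the cost, and the permuted
#' reference is retained as the ground-truth construction.
#'
#' With `min_rep`/`max_rep` `NULL` the range is per-locus
#' `ref_repeats - pad .. ref_repeats + pad`, clipped at 1.
#'
#' @param panel An [str_panel()] tibble.
#' @param min_rep,max_rep Fixed permutation range (optional).
#' @param pad Per-locus half-range used when `min_rep`/`max_rep` are `NULL`.
#'
#' @return A tibble with columns `record_id`, `locus_id`, `repeats`, `seq`.
#' @export
permuted_reference <- function(panel, min_rep = NULL, max_rep = NULL,
                               pad = 20L) {
  if (nrow(panel) == 0) {
    abort("empty panel", class = "strwga_input_error")
  }
  if (!is.null(min_rep) || !is.null(max_rep)) {
    stopifnot(!is.null(min_rep), !is.null(max_rep),
              min_rep >= 1, min_rep <= max_rep)
    lo <- rep(as.integer(min_rep), nrow(panel))
    hi <- rep(as.integer(max_rep), nrow(panel))
  } else {
    lo <- pmax(1L, panel$ref_repeats - as.integer(pad))
    hi <- panel$ref_repeats + as.integer(pad)
  }
  idx <- rep(seq_len(nrow(panel)), hi - lo + 1L)
  reps <- unlist(lapply(seq_len(nrow(panel)), function(i) lo[i]:hi[i]))
  tibble(record_id = paste0(panel$locus_id[idx], "|", reps),
         locus_id = panel$locus_id[idx],
         repeats = reps,
         seq = paste0(panel$left_flank[idx],
                      stringr::str_dup(panel$unit[idx], reps),
                      panel$right_flank[idx]))
}

#' Write a permuted reference as FASTA
#'
#' @param permuted A tibble from [permuted_reference()].
#' @param path Output FASTA path (wrapped at 80 columns).
#' @return `path`, invisibly.
#' @export
write_permuted_reference <- function(permuted, path) {
  x <- Biostrings::DNAStringSet(setNames(permuted$seq, permuted$record_id))
  Biostrings::writeXStringSet(x, path, width = 80)
  invisible(path)
}
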