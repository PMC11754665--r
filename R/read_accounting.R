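#' Aggregated read-assignment table for one kit/replicate
#'
#' Read counts by assignment category: A = uniquely mapped and tagged with a
#' called cell's barcode, B = uniquely mapped and tagged with a non-cell
#' barcode, C = all other reads (unmapped, untagged, duplicates, ...).
#' Category counts must sum exactly to the total.
#'
#' @param kit_id,replicate_id identifiers.
#' @param n_category_a,n_category_b,n_category_c category read counts.
#' @param total_reads total input reads; defaults to the category sum and is
#'   checked against it when given.
#' @return object of class `read_assignment_table`.
#' @export
read_assignment_table <- function(kit_id, replicate_id,
                                  n_category_a, n_category_b, n_category_c,
                                  total_reads = NULL) {
  for (n in list(n_category_a, n_category_b, n_category_c))
    stopifnot_msg(is_count(n), "category counts must be non-negative integers")
  s <- n_category_a + n_category_b + n_category_c
  if (is.null(total_reads)) total_reads <- s
  stopifnot_msg(total_reads == s,
                "category counts must sum exactly to total_reads")
  structure(list(kit_id = kit_id, replicate_id = replicate_id,
                 n_category_a = n_category_a, n_category_b = n_category_b,
                 n_category_c = n_category_c, total_reads = total_reads),
            class = "read_assignment_table")
}

#' @export
print.read_assignment_table <- function(x, ...) {
  cat("<read_assignment_table> ", x$kit_id, "/", x$replicate_id,
      ": A=", x$n_category_a, " B=", x$n_category_b, " C=", x$n_category_c,
      " total=", x$total_reads, "\n", sep = "")
  invisible(x)
}

#' Read-utilization fractions
#'
#' Splits the total reads of a [read_assignment_table()] into the usable
#' fraction (category A: mapped with a cell barcode), the non-cell-barcode
#' fraction (B) and the unusable remainder (C). The three fractions sum to 1.
#'
#' @param table a [read_assignment_table()].
#' @return named numeric vector `c(usable, noncell, unusable)`.
#' @export
read_utilization <- function(table) {
  stopifnot_msg(inherits(table, "read_assignment_table"),
                "`table` must be a read_assignment_table")
  stopifnot_msg(table$total_reads > 0, "total_reads must be > 0")
  c(usable = table$n_category_a / table$total_reads,
    noncell = table$n_category_b / table$total_reads,
    unusable = table$n_category_c / table$total_reads)
}

#' UMI recovery: total UMIs per total input read
#'
#' The efficiency of converting sequenced reads into countable deduplicated
#' molecules. Values above 1 are reported unclamped with a warning since
#' they indicate inconsistent inputs.
#'
#' @param total_umis total UMI counts in the matrix.
#' @param total_reads total input FASTQ reads; must be > 0.
#' @return a single fraction.
#' @export
umi_recovery <- function(total_umis, total_reads) {
  stopifnot_msg(is.numeric(total_umis) && total_umis >= 0,
                "`total_umis` must be non-negative")
  stopifnot_msg(is.numeric(total_reads) && total_reads > 0,
                "`total_reads` must be > 0")
  r <- total_umis / total_reads
  if (r > 1)
    warning("UMI recovery > 1: more UMIs than input reads; check inputs")
  r
}

#' Barcode rank profile
#'
#' Per-barcode UMI counts with a ranking sorted by descending count, ties
#' broken lexicographically by barcode so the ranking is stable.
#'
#' @param counts named numeric vector: barcode -> UMI count.
#' @return object of class `barcode_rank_profile` with elements `counts`
#'   (as given) and `ranked` (sorted).
#' @export
barcode_rank_profile <- function(counts) {
  stopifnot_msg(is.numeric(counts) && !is.null(names(counts)) &&
                  all(nzchar(names(counts))),
                "`counts` must be a named numeric vector")
  stopifnot_msg(!anyDuplicated(names(counts)), "barcodes must be unique")
  stopifnot_msg(all(counts >= 0), "counts must be non-negative")
  ord <- order(-counts, names(counts), method = "radix")
  structure(list(counts = counts, ranked = counts[ord]),
            class = "barcode_rank_profile")
}

#' @export
print.barcode_rank_profile <- function(x, ...) {
  cat("<barcode_rank_profile> ", length(x$counts), " barcodes, top count ",
      if (length(x$ranked)) x$ranked[1] else NA, "\n", sep = "")
  invisible(x)
}

#' @export
length.barcode_rank_profile <- function(x) length(x$counts)

#' Anchor count M of the Fluent threshold formula
#'
#' Scans the ranked barcodes from rank 2 downward and returns the count of
#' the first barcode whose relative drop from its predecessor,
#' (prev - cur)/prev, does not exceed 10%. If no rank qualifies (e.g. a
#' strictly geometric profile) the last ranked count is returned with a
#' warning.
#'
#' @param profile a [barcode_rank_profile()] with at least 2 barcodes of
#'   positive count.
#' @param max_drop maximal qualifying relative drop (default 0.10).
#' @return the anchor UMI count M.
#' @export
fluent_find_m <- function(profile, max_drop = 0.10) {
  stopifnot_msg(inherits(profile, "barcode_rank_profile"),
                "`profile` must be a barcode_rank_profile")
  ranked <- profile$ranked[profile$ranked > 0]
  stopifnot_msg(length(ranked) >= 2, "need >= 2 barcodes with positive counts")
  prev <- ranked[-length(ranked)]
  cur <- ranked[-1]
  ok <- (prev - cur) / prev <= max_drop
  if (any(ok)) return(unname(cur[which(ok)[1]]))
  warning("no rank with drop <= ", max_drop, "; returning last ranked count")
  unname(ranked[length(ranked)])
}

#' Fluent sensitivity-level UMI thresholds
#'
#' The five cell-calling thresholds `T_i = M * 10^(-(0.5 + 0.25 * L_i))` for
#' sensitivity levels `L_i = 1..5`, real-valued (no rounding). Consecutive
#' thresholds stand in the exact ratio `10^(-0.25)`.
#'
#' @param M anchor UMI count (>= 0), typically from [fluent_find_m()].
#' @return object of class `fluent_thresholds`: list with `M`, `levels`,
#'   `thresholds`.
#' @export
fluent_thresholds <- function(M) {
  stopifnot_msg(is.numeric(M) && length(M) == 1L && is.finite(M) && M >= 0,
                "`M` must be a single non-negative number")
  levels <- 1:5
  structure(list(M = M, levels = levels,
                 thresholds = M * 10^(-(0.5 + 0.25 * levels))),
            class = "fluent_thresholds")
}

#' @export
print.fluent_thresholds <- function(x, ...) {
  cat("<fluent_thresholds> M =", x$M, "\n")
  print(setNames(signif(x$thresholds, 6), paste0("L", x$levels)))
  invisible(x)
}

#' Threshold-based (Fluent-style) cell calling
#'
#' Calls every barcode whose UMI count is at or above the threshold of the
#' chosen sensitivity level. With `level = "auto"` the level whose called
#' count is closest to `target` is selected (ties broken toward the lower
#' level).
#'
#' @param profile a [barcode_rank_profile()].
#' @param level integer 1..5 or `"auto"`.
#' @param target targeted cell count, required for `"auto"`.
#' @return list with `barcodes` (called set, in ranked order), `level`,
#'   `threshold`, `M`.
#' @export
fluent_call_cells <- function(profile, level = "auto", target = NULL) {
  stopifnot_msg(inherits(profile, "barcode_rank_profile"),
                "`profile` must be a barcode_rank_profile")
  stopifnot_msg(length(profile$counts) > 0, "empty profile")
  th <- fluent_thresholds(fluent_find_m(profile))
  call_at <- function(l) names(profile$ranked)[profile$ranked >= th$thresholds[l]]
  if (identical(level, "auto")) {
    stopifnot_msg(is_count(target) && target > 0,
                  "`target` must be given (positive) for level = \"auto\"")
    ncalled <- vapply(th$levels, function(l) length(call_at(l)), integer(1))
    level <- th$levels[which.min(abs(ncalled - target))]
  } else {
    stopifnot_msg(is.numeric(level) && level %in% 1:5,
                  "`level` must be in 1..5 or \"auto\"")
    level <- as.integer(level)
  }
  list(barcodes = call_at(level), level = level,
       threshold = th$thresholds[level], M = th$M)
}

#' Fixed-count (Honeycomb-style) cell calling
#'
#' Returns exactly the top `n` barcodes by UMI count, ties broken
#' lexicographically by barcode.
#'
#' @param profile a [barcode_rank_profile()].
#' @param n number of barcodes to call; must not exceed the profile size.
#' @return character vector of `n` barcodes in ranked order.
#' @export
fixed_count_call <- function(profile, n) {
  stopifnot_msg(inherits(profile, "barcode_rank_profile"),
                "`profile` must be a barcode_rank_profile")
  stopifnot_msg(is_count(n), "`n` must be a count")
  stopifnot_msg(n <= length(profile$counts),
                "`n` exceeds the number of barcodes in the profile")
  names(profile$ranked)[seq_len(n)]
}

#' Cell recovery rate in percent
#'
#' @param called number of called cells.
#' @param targeted targeted cell count (> 0).
#' @return `100 * called / targeted`.
#' @export
recovery_rate <- function(called, targeted) {
  stopifnot_msg(is.numeric(targeted) && targeted > 0, "`targeted` must be > 0")
  stopifnot_msg(is.numeric(called) && called >= 0, "`called` must be >= 0")
  100 * called / targeted
}
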