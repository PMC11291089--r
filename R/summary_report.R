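#' Call the quality category of one locus
#'
#' Combines the per-position evidence of a locus (union over its
#' haplotype intervals) into a single categorical call. The mismatch
#' flag is raised when flagged-position evidence clears a floor: at
#' least one merged flagged interval of `min_flag_interval` bp (default
#' 100), or flagged positions covering at least `flag_frac_min` of the
#' locus (default 0.5%). The break flag is raised by any coverage break
#' of at least `min_break_len` bp (default 10) whose category is not
#' `contig_end`. The category applies the precedence
#' mismatch > break > good. The evidence floors are this package's
#' defaults, set so that defect-free simulations call "good"; tune them
#' for other data regimes.
#'
#' @param flags an [ig_flags][flag_poorly_supported], or a list of them
#'   (one per haplotype interval of the locus).
#' @param breaks an [ig_breaks][detect_coverage_breaks] with `category`
#'   column (see [classify_breaks()]), or a list of them.
#' @param locus_length total analyzed length (bp) across the locus's
#'   intervals.
#' @param min_flag_interval,flag_frac_min,min_break_len evidence floors,
#'   see Details.
#' @return list of class `ig_locus_call`: `mismatch_flag`, `break_flag`,
#'   `any_error`, `category` (`"mismatch"`, `"break"` or `"good"`), and
#'   the evidence tallies.
#' @export
call_locus <- function(flags, breaks, locus_length,
                       min_flag_interval = 100L,
                       flag_frac_min = 0.005,
                       min_break_len = 10L) {
  if (inherits(flags, "ig_flags")) flags <- list(flags)
  if (is.data.frame(breaks)) breaks <- list(breaks)
  n_flagged <- sum(vapply(flags, `[[`, 0L, "n_flagged"))
  max_iv <- max(c(0L, unlist(lapply(flags, function(f) f$intervals$length))))
  frac <- n_flagged / locus_length
  mismatch_flag <- max_iv >= min_flag_interval || frac >= flag_frac_min
  bk <- do.call(rbind, lapply(breaks, as.data.frame))
  if (is.null(bk)) bk <- data.frame(length = integer(), category = character())
  sig <- bk$length >= min_break_len & bk$category != "contig_end"
  break_flag <- any(sig)
  structure(list(
    mismatch_flag = mismatch_flag,
    break_flag = break_flag,
    any_error = mismatch_flag || break_flag,
    category = if (mismatch_flag) "mismatch" else
      if (break_flag) "break" else "good",
    n_flagged_positions = n_flagged,
    flagged_fraction = frac,
    max_flag_interval = max_iv,
    n_significant_breaks = sum(sig),
    locus_length = locus_length),
    class = "ig_locus_call")
}

#' @export
print.ig_locus_call <- function(x, ...) {
  cat("ig_locus_call:", x$category,
      sprintf("(%d flagged positions, %d significant breaks)\n",
              x$n_flagged_positions, x$n_significant_breaks))
  invisible(x)
}

#' Aggregate per-species locus calls into a summary table
#'
#' Groups one call per (species, locus) by locus class and haplotype
#' resolution and tabulates the mismatch / break / good categories with
#' percentages to 0.1%, plus per-locus any-error totals across
#' resolutions.
#'
#' Counting modes: in `"nonexclusive"` mode (default) a species counts
#' in the mismatch column if its mismatch flag is set and in the breaks
#' column if its break flag is set, so a species with both errors
#' appears in both columns and row counts can exceed the group total.
#' In `"exclusive"` mode mismatch takes precedence over break and the
#' three columns partition the group. In both modes
#' `good = total - any_error` exactly.
#'
#' @param calls data.frame with columns `species`, `locus`, `resolution`
#'   (`"resolved"`/`"unresolved"`), `mismatch_flag`, `break_flag`
#'   (logical or 0/1). Duplicate (species, locus) pairs are an error.
#' @param mode `"nonexclusive"` or `"exclusive"`.
#' @return list of class `ig_summary`: `by_group` (one row per locus x
#'   resolution with counts and percentages) and `any_error` (one row
#'   per locus: total species, any-error count and percentage).
#' @export
aggregate_species <- function(calls, mode = c("nonexclusive", "exclusive")) {
  mode <- match.arg(mode)
  need <- c("species", "locus", "resolution", "mismatch_flag", "break_flag")
  if (!all(need %in% names(calls)))
    stop("calls must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(calls[, c("species", "locus")]))
    stop("duplicate (species, locus) pair(s) in calls")
  calls$mismatch_flag <- as.logical(calls$mismatch_flag)
  calls$break_flag <- as.logical(calls$break_flag)
  if (!all(calls$resolution %in% c("resolved", "unresolved")))
    stop("resolution must be 'resolved' or 'unresolved'")

  grp <- unique(calls[, c("locus", "resolution")])
  grp <- grp[order(match(grp$locus, .LOCUS_CLASSES),
                   match(grp$resolution, c("resolved", "unresolved"))), ,
             drop = FALSE]
  by_group <- do.call(rbind, lapply(seq_len(nrow(grp)), function(i) {
    g <- calls[calls$locus == grp$locus[i] &
                 calls$resolution == grp$resolution[i], ]
    n <- nrow(g)
    n_mm <- sum(g$mismatch_flag)
    n_bk <- if (mode == "nonexclusive") sum(g$break_flag) else
      sum(g$break_flag & !g$mismatch_flag)
    n_good <- sum(!g$mismatch_flag & !g$break_flag)
    data.frame(locus = grp$locus[i], resolution = grp$resolution[i],
               n = n,
               n_mismatch = n_mm, pct_mismatch = round1(100 * n_mm / n),
               n_break = n_bk, pct_break = round1(100 * n_bk / n),
               n_good = n_good, pct_good = round1(100 * n_good / n),
               stringsAsFactors = FALSE)
  }))
  any_error <- do.call(rbind, lapply(unique(grp$locus), function(lc) {
    g <- calls[calls$locus == lc, ]
    n <- nrow(g)
    n_err <- sum(g$mismatch_flag | g$break_flag)
    data.frame(locus = lc, n = n, n_any_error = n_err,
               pct_any_error = round1(100 * n_err / n),
               stringsAsFactors = FALSE)
  }))
  structure(list(by_group = by_group, any_error = any_error, mode = mode),
            class = "ig_summary")
}

#' @export
print.ig_summary <- function(x, ...) {
  cat("Summary of assembly quality by locus (", x$mode, " counting)\n",
      sep = "")
  print(x$by_group, row.names = FALSE)
  cat("\nAny-error totals per locus:\n")
  print(x$any_error, row.names = FALSE)
  invisible(x)
}

#' Read / write per-species calls tables
#'
#' The calls TSV (`species`, `locus`, `resolution`, `mismatch_flag`,
#' `break_flag`) lets summary arithmetic be reproduced from published
#' per-group counts without re-evaluating any genome.
#'
#' @param path TSV path.
#' @return data.frame of calls.
#' @export
read_calls_tsv <- function(path) {
  df <- read_tsv_commented(path)
  need <- c("species", "locus", "resolution", "mismatch_flag", "break_flag")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("calls table missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_calls_tsv
#' @param calls data.frame of calls.
#' @export
write_calls_tsv <- function(calls, path) {
  write_tsv_commented(calls, path,
                      "per-species locus calls; flags are 0/1")
  invisible(path)
}
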