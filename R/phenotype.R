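#' Read litter-size records
#'
#' Reads a phenotype CSV with columns `sow,parity,fys,tnb` (sow id, parity
#' number, farm-year-season class, total number born).
#'
#' @param path Path to the CSV file (header required).
#' @return A tibble with `sow` (character), `parity` (integer), `fys`
#'   (character), `tnb` (numeric).
#' @export
read_litter_records <- function(path) {
  df <- utils::read.csv(path, strip.white = TRUE)
  need <- c("sow", "parity", "fys", "tnb")
  if (!all(need %in% names(df))) {
    abort(paste0("phenotype file must have columns sow,parity,fys,tnb; found: ",
                 paste(names(df), collapse = ",")))
  }
  tibble(sow = as.character(df$sow), parity = as.integer(df$parity),
         fys = as.character(df$fys), tnb = as.numeric(df$tnb))
}

#' Apply the litter-record editing rules
#'
#' Standard edits for total-number-born records: litters with fewer than
#' `min_tnb` piglets are dropped, litters of `cap_tnb` or more are set to
#' `cap_tnb`, and parities of `max_parity` or higher are pooled into one
#' class. Editing is idempotent.
#'
#' @param records A data frame with at least `tnb` and `parity` columns.
#' @param min_tnb Minimum litter size kept (default 4).
#' @param cap_tnb Upper cap on litter size (default 27).
#' @param max_parity Highest distinct parity class (default 10).
#' @return The edited tibble, with an `"edit_report"` attribute (tibble of
#'   rule and count) retrievable via [edit_report()].
#' @export
edit_records <- function(records, min_tnb = 4, cap_tnb = 27, max_parity = 10) {
  records <- as_tibble(records)
  if (any(records$tnb < 0)) abort("negative TNB value")
  if (any(records$parity < 1)) abort("parity must be >= 1")
  drop <- records$tnb < min_tnb
  capped <- !drop & records$tnb >= cap_tnb & records$tnb != cap_tnb
  pooled <- !drop & records$parity > max_parity
  out <- records[!drop, ]
  out$tnb <- pmin(out$tnb, cap_tnb)
  out$parity <- pmin(out$parity, max_parity)
  report <- tibble(rule = c(paste0("tnb_below_", min_tnb, "_dropped"),
                            paste0("tnb_capped_at_", cap_tnb),
                            paste0("parity_pooled_at_", max_parity)),
                   n = c(sum(drop), sum(capped), sum(pooled)))
  attr(out, "edit_report") <- report
  out
}

#' @rdname edit_records
#' @param x A tibble returned by [edit_records()].
#' @export
edit_report <- function(x) attr(x, "edit_report")

#' Per-sow summaries for the conventional bivariate analysis
#'
#' Collapses repeated litter records to one row per sow: number of litters,
#' mean TNB, and the natural log of the unbiased (n-1 denominator) sample
#' variance of TNB. Sows with fewer than `min_parities` litters are omitted;
#' sows with zero sample variance are dropped with a warning (the log is
#' undefined and such sows carry no dispersion information). An `fys` column,
#' if present, is carried over as the sow's most frequent class.
#'
#' @param records Edited litter records ([edit_records()]).
#' @param min_parities Minimum litters per sow (default 3).
#' @return A tibble `sow, n_litters, mean_tnb, log_var_tnb` (plus `fys`).
#' @export
summarize_sows <- function(records, min_parities = 3) {
  records <- as_tibble(records)
  smry <- dplyr::summarise(
    dplyr::group_by(records, .data$sow),
    n_litters = dplyr::n(),
    mean_tnb = mean(.data$tnb),
    var_tnb = stats::var(.data$tnb),
    .groups = "drop")
  if ("fys" %in% names(records)) {
    fys_mode <- dplyr::summarise(
      dplyr::group_by(records, .data$sow),
      fys = names(sort(table(.data$fys), decreasing = TRUE))[1],
      .groups = "drop")
    smry <- dplyr::left_join(smry, fys_mode, by = "sow")
  }
  smry <- smry[smry$n_litters >= min_parities, ]
  zero <- smry$var_tnb == 0
  if (any(zero)) {
    warn(paste0(sum(zero), " sow(s) with zero TNB variance excluded ",
                "(log variance undefined)"))
    smry <- smry[!zero, ]
  }
  smry$log_var_tnb <- log(smry$var_tnb)
  smry$var_tnb <- NULL
  smry
}
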