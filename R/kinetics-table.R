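#' Assemble a kinetics summary table with fold changes
#'
#' Builds the per-variant, per-nucleotide summary of nucleotide-exchange and
#' hydrolysis kinetics: `k_on`, `k_off`, the derived affinity
#' `K_d = k_off/k_on`, and `k_cat`, plus a block of derived fold changes —
#' mutant-versus-reference ratios of `k_on`, `k_off` and `K_d` per
#' nucleotide, within-variant GDP/GppNHp `k_off` and `K_d` ratios, and the
#' exchange-versus-hydrolysis ratio `k_off(GDP)/k_cat` that diagnoses
#' GTP-loading. Every fold change is a quotient of table entries.
#'
#' Affinity fold changes use the `kd_printed_uM` column when both operands
#' carry one: published affinities are computed from unrounded rates, so
#' ratios of re-derived `k_off/k_on` values would compound the rounding error
#' of two rate constants. Where printed affinities are unavailable the
#' computed `kd_uM` is used.
#'
#' @param entries Data frame with columns `variant`, `nucleotide` (`"GDP"` or
#'   `"GppNHp"`), `k_on_per_uM_s` (`NA` when binding was not observed),
#'   `k_off_per_s`, and optionally `kcat_per_s` (per variant) and
#'   `kd_printed_uM`. [ttn5_rates()] returns a ready-made input.
#' @param reference_variant Variant used as denominator for mutant/reference
#'   ratios (default `"WT"`).
#' @param fold_changes `NULL` (default) computes fold changes when the
#'   reference variant is present and omits them otherwise; `TRUE` requires
#'   the reference (error if absent); `FALSE` omits them.
#' @return A `kinetics_table`: list with `table` (tibble: `variant`,
#'   `nucleotide`, `k_on_per_uM_s`, `k_off_per_s`, `kd_uM`, `kcat_per_s`) and
#'   `fold_changes` (tibble: `quantity`, `comparison`, `nucleotide`, `fold`;
#'   `NULL` when omitted). `kd_uM` is always `k_off/k_on`, `NA` where `k_on`
#'   is absent.
#' @export
#' @examples
#' kt <- build_kinetics_table(ttn5_rates())
#' kt$fold_changes
build_kinetics_table <- function(entries, reference_variant = "WT",
                                 fold_changes = NULL) {
  entries <- as_tibble(entries)
  need <- c("variant", "nucleotide", "k_on_per_uM_s", "k_off_per_s")
  if (!all(need %in% names(entries))) {
    abort_input(paste0("`entries` needs columns: ",
                       paste(need, collapse = ", "), "."))
  }
  if (!"kcat_per_s" %in% names(entries)) entries$kcat_per_s <- NA_real_
  if (!"kd_printed_uM" %in% names(entries)) {
    entries$kd_printed_uM <- NA_real_
  }
  if (!any(table(entries$variant) >= 2L)) {
    abort_input("Need at least one variant measured with both nucleotides.")
  }

  tab <- entries |>
    dplyr::mutate(
      kd_uM = dplyr::if_else(
        !is.na(.data$k_on_per_uM_s) & .data$k_on_per_uM_s > 0,
        .data$k_off_per_s / .data$k_on_per_uM_s, NA_real_),
      # affinity used for ratio formation (printed preferred, see Details)
      .kd_ratio_basis = dplyr::coalesce(.data$kd_printed_uM, .data$kd_uM)
    ) |>
    dplyr::select("variant", "nucleotide", "k_on_per_uM_s", "k_off_per_s",
                  "kd_uM", "kcat_per_s", "kd_printed_uM", ".kd_ratio_basis")

  has_ref <- reference_variant %in% tab$variant
  want_fc <- if (is.null(fold_changes)) has_ref else isTRUE(fold_changes)
  fc <- NULL
  if (want_fc) {
    if (!has_ref) {
      abort_input(sprintf(
        "Fold changes requested but reference variant '%s' is not in the table.",
        reference_variant))
    }
    fc <- compute_fold_changes(tab, reference_variant)
  }

  out_tab <- dplyr::select(tab, -".kd_ratio_basis")
  structure(list(table = out_tab, fold_changes = fc,
                 reference_variant = if (has_ref) reference_variant else NULL),
            class = "kinetics_table")
}

compute_fold_changes <- function(tab, ref) {
  entry <- function(variant, nucleotide, col) {
    v <- tab[[col]][tab$variant == variant & tab$nucleotide == nucleotide]
    if (length(v) != 1L) NA_real_ else v
  }
  rows <- list()
  add <- function(quantity, comparison, nucleotide, num, den) {
    if (is.na(num) || is.na(den) || den == 0) return()
    rows[[length(rows) + 1L]] <<- tibble(
      quantity = quantity, comparison = comparison,
      nucleotide = nucleotide, fold = num / den)
  }

  mutants <- setdiff(unique(tab$variant), ref)
  for (v in mutants) {
    for (nt in intersect(tab$nucleotide[tab$variant == v],
                         tab$nucleotide[tab$variant == ref])) {
      cmp <- paste0(v, "/", ref)
      add("k_on", cmp, nt,
          entry(v, nt, "k_on_per_uM_s"), entry(ref, nt, "k_on_per_uM_s"))
      add("k_off", cmp, nt,
          entry(v, nt, "k_off_per_s"), entry(ref, nt, "k_off_per_s"))
      add("K_d", cmp, nt,
          entry(v, nt, ".kd_ratio_basis"), entry(ref, nt, ".kd_ratio_basis"))
    }
  }
  for (v in unique(tab$variant)) {
    add("k_off", "GDP/GppNHp", v,
        entry(v, "GDP", "k_off_per_s"), entry(v, "GppNHp", "k_off_per_s"))
    add("K_d", "GDP/GppNHp", v,
        entry(v, "GDP", ".kd_ratio_basis"),
        entry(v, "GppNHp", ".kd_ratio_basis"))
    add("k_off_GDP/k_cat", "within", v,
        entry(v, "GDP", "k_off_per_s"), entry(v, "GDP", "kcat_per_s"))
  }
  dplyr::bind_rows(rows)
}

#' @export
print.kinetics_table <- function(x, ...) {
  cat("<kinetics_table>\n")
  print(x$table)
  if (!is.null(x$fold_changes)) {
    cat(sprintf("\nFold changes (reference: %s)\n", x$reference_variant))
    print(x$fold_changes)
  }
  invisible(x)
}

#' Write a kinetics table to CSV and JSON
#'
#' @param kt A `kinetics_table` from [build_kinetics_table()].
#' @param path Output path without extension; writes `<path>.csv`,
#'   `<path>_fold_changes.csv` (when present) and `<path>.json`.
#' @return Invisibly, the paths written.
#' @export
write_kinetics_table <- function(kt, path) {
  stopifnot(inherits(kt, "kinetics_table"))
  paths <- character()
  csv <- paste0(path, ".csv")
  readr::write_csv(kt$table, csv)
  paths <- c(paths, csv)
  if (!is.null(kt$fold_changes)) {
    fcsv <- paste0(path, "_fold_changes.csv")
    readr::write_csv(kt$fold_changes, fcsv)
    paths <- c(paths, fcsv)
  }
  js <- paste0(path, ".json")
  jsonlite::write_json(list(table = kt$table, fold_changes = kt$fold_changes),
                       js, dataframe = "rows", na = "null", digits = NA)
  invisible(c(paths, js))
}
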