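#' Per-well cfDNA mutation data
#'
#' Container for the quantities behind the omega score: for each sequencing
#' well of a plasma sample, the number of unique identifier (UID) template
#' molecules observed and two p-values locating the well's mutant allele
#' frequency in the cancer and normal reference distributions.
#'
#' @param uids_per_well positive integer UID counts, one per well.
#' @param p_cancer,p_normal p-values in (0, 1], one per well.
#' @return An object of class `"omega_well_data"`.
#' @export
omega_well_data <- function(uids_per_well, p_cancer, p_normal) {
  w <- length(uids_per_well)
  if (w < 1L) stop("at least one well is required", call. = FALSE)
  if (length(p_cancer) != w || length(p_normal) != w) {
    stop("uids_per_well, p_cancer and p_normal must have equal length",
         call. = FALSE)
  }
  if (any(uids_per_well <= 0) || any(uids_per_well != floor(uids_per_well))) {
    stop("UID counts must be positive integers", call. = FALSE)
  }
  if (any(p_cancer <= 0) || any(p_cancer > 1) ||
      any(p_normal <= 0) || any(p_normal > 1)) {
    stop("domain error: p-values must lie in (0, 1]", call. = FALSE)
  }
  structure(list(uids_per_well = as.numeric(uids_per_well),
                 p_cancer = as.numeric(p_cancer),
                 p_normal = as.numeric(p_normal)),
            class = "omega_well_data")
}

#' cfDNA mutation omega score
#'
#' Summarizes a sample's per-well mutant-allele-frequency evidence into a
#' single score: the UID-weighted sum of log-ratios of the cancer versus
#' normal p-values,
#' \deqn{\Omega = \sum_{i=1}^{w} w_i \, \ln(p_i^C / p_i^N),}
#' where \eqn{w_i = UIDs_i / \sum_j UIDs_j}. The score is invariant to
#' rescaling all UID counts and is zero when the two p-values agree in
#' every well.
#'
#' @param wells an [omega_well_data()] object.
#' @return A finite numeric scalar.
#' @export
compute_omega <- function(wells) {
  stopifnot(inherits(wells, "omega_well_data"))
  wt <- wells$uids_per_well / sum(wells$uids_per_well)
  sum(wt * log(wells$p_cancer / wells$p_normal))
}

#' Read per-well omega input from CSV
#'
#' Expects columns `uids`, `p_cancer`, `p_normal` (a `well` column, if
#' present, is ignored — rows are the wells).
#'
#' @param path CSV file path.
#' @return An [omega_well_data()] object.
#' @export
read_well_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("uids", "p_cancer", "p_normal")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("schema error: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  omega_well_data(df$uids, df$p_cancer, df$p_normal)
}
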