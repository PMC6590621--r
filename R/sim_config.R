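#' Simulation configuration
#'
#' Parameters of the synthetic two-condition RNA-seq experiment.  Defaults
#' reproduce the study design the package models: two conditions ("con",
#' "ldl") in quadruplicate, single-end reads, a mitochondrial read fraction
#' of 4.5% in control vs 11.2% under treatment, a nuclear isoform mixture
#' that shifts from 0.8/0.2 (full-length/truncated) to 0.5/0.5, and an
#' unchanged mitochondrial precursor fraction of 5%.
#'
#' @param n_replicates_per_condition Biological replicates per condition.
#' @param reads_per_sample Single-end reads simulated per sample.
#' @param read_length Read length in nucleotides (>= 20).
#' @param mito_fraction Named list/vector, one probability per condition:
#'   chance that a read originates from the mitochondrial compartment.
#' @param isoform_mixture Named list, one numeric vector per condition
#'   mapping isoform id to sampling probability (must sum to 1).
#' @param precursor_fraction Named list/vector, one probability per
#'   condition: chance that a mitochondrial read derives from the
#'   unprocessed genomic precursor rather than a mature transcript unit.
#' @param seed Integer master seed; per-sample streams are derived from it
#'   together with the condition and replicate index.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(reads_per_sample = 1000)
#' cfg$conditions
#' @export
sim_config <- function(n_replicates_per_condition = 4L,
                       reads_per_sample = 100000L,
                       read_length = 100L,
                       mito_fraction = c(con = 0.045, ldl = 0.112),
                       isoform_mixture = list(
                         con = c(NUC1.full = 0.8, NUC1.short = 0.2),
                         ldl = c(NUC1.full = 0.5, NUC1.short = 0.5)
                       ),
                       precursor_fraction = c(con = 0.05, ldl = 0.05),
                       seed = 1L) {
  conditions <- names(mito_fraction)
  if (is.null(conditions) || any(conditions == "")) {
    stop("mito_fraction must be named by condition")
  }
  if (!identical(sort(conditions), sort(names(isoform_mixture))) ||
      !identical(sort(conditions), sort(names(precursor_fraction)))) {
    stop("mito_fraction, isoform_mixture and precursor_fraction must share ",
         "the same condition names")
  }
  mito_fraction <- unlist(mito_fraction)[conditions]
  precursor_fraction <- unlist(precursor_fraction)[conditions]
  stopifnot(
    length(conditions) >= 1,
    n_replicates_per_condition >= 1,
    reads_per_sample >= 0,
    read_length >= 20,
    all(mito_fraction >= 0 & mito_fraction <= 1),
    all(precursor_fraction >= 0 & precursor_fraction <= 1)
  )
  for (cond in conditions) {
    mix <- isoform_mixture[[cond]]
    if (is.null(names(mix)) || any(names(mix) == "")) {
      stop("isoform_mixture[['", cond, "']] must be named by isoform id")
    }
    if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9) {
      stop("isoform_mixture[['", cond, "']] must be non-negative and sum to 1")
    }
  }
  structure(
    list(
      conditions = conditions,
      n_replicates_per_condition = as.integer(n_replicates_per_condition),
      reads_per_sample = as.integer(reads_per_sample),
      read_length = as.integer(read_length),
      mito_fraction = mito_fraction,
      isoform_mixture = lapply(isoform_mixture[conditions], unlist),
      precursor_fraction = precursor_fraction,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  conditions:          ", paste(x$conditions, collapse = ", "), "\n")
  cat("  replicates/condition:", x$n_replicates_per_condition, "\n")
  cat("  reads/sample:        ", x$reads_per_sample, "\n")
  cat("  read length:         ", x$read_length, "nt\n")
  cat("  mito fraction:       ",
      paste(sprintf("%s=%.3f", x$conditions, x$mito_fraction), collapse = " "),
      "\n")
  cat("  precursor fraction:  ",
      paste(sprintf("%s=%.3f", x$conditions, x$precursor_fraction),
            collapse = " "), "\n")
  cat("  seed:                ", x$seed, "\n")
  invisible(x)
}

# Deterministic per-sample seed below 2^31, derived from the master seed and
# the sample's position in the design.
derive_seed <- function(seed, condition_index, replicate) {
  (as.numeric(seed) * 2654435761 + condition_index * 97561 +
     replicate * 7919) %% 2147483647
}
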