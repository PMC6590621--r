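# ---- qPCR relative quantification on the 2^-dCt scale -----------------------

#' Relative quantity from a Ct pair
#'
#' `rq = 2^-(ct_target - ct_reference)`, assuming perfect doubling per PCR
#' cycle.  One cycle earlier therefore means exactly twofold more
#' template.  Vectorized over both arguments.
#'
#' @param ct_target,ct_reference Cycle-threshold values (0 < Ct < 60).
#' @return Relative quantity (dimensionless, > 0).
#' @examples
#' relative_quantity(26, 25)  # 0.5
#' @export
relative_quantity <- function(ct_target, ct_reference) {
  if (any(ct_target <= 0) || any(ct_target >= 60) ||
      any(ct_reference <= 0) || any(ct_reference >= 60)) {
    stop("Ct values must lie in (0, 60)")
  }
  2^-(ct_target - ct_reference)
}

#' Summarize a qPCR Ct table
#'
#' Technical replicates of the same (sample, target) are averaged on the Ct
#' scale (i.e. geometrically on the quantity scale); each sample's targets
#' are then quantified against its own reference-target Ct; per target, the
#' two conditions are compared with an unpaired two-sided Student's t-test
#' and summarized as mean +/- SEM.  Samples lacking a reference Ct are
#' excluded with a warning.  Optional mock (no-RT) records flag a target as
#' possibly contaminated when the mock Ct comes within 5 cycles of the RT
#' Ct; flagged targets are reported, not excluded.
#'
#' @param records Tibble `sample_id`, `condition`, `target`, `ct`, optional
#'   logical `is_mock`.
#' @param reference Name of the reference target (e.g. "RPL32").
#' @return List: `rq` (per sample/target relative quantities with a
#'   `contaminated` flag), `summary` (per target: condition means, SEM, t,
#'   df, p), `excluded_samples`.
#' @export
summarize_qpcr <- function(records, reference) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("sample_id", "condition", "target", "ct") %in%
                  names(records)))
  if (!nrow(records)) stop("empty Ct table")
  if (any(records$ct <= 0 | records$ct >= 60)) {
    stop("Ct values must lie in (0, 60)")
  }
  if (any(records$target == "")) stop("empty target name")
  if (!"is_mock" %in% names(records)) records$is_mock <- FALSE
  records$is_mock[is.na(records$is_mock)] <- FALSE

  rt <- records %>%
    filter(!is_mock) %>%
    group_by(sample_id, condition, target) %>%
    summarise(ct = mean(ct), .groups = "drop")
  mock <- records %>%
    filter(is_mock) %>%
    group_by(sample_id, target) %>%
    summarise(mock_ct = mean(ct), .groups = "drop")

  refs <- rt %>% filter(target == reference) %>%
    select(sample_id, reference_ct = ct)
  excluded <- setdiff(unique(rt$sample_id), refs$sample_id)
  if (length(excluded)) {
    warning(length(excluded), " sample(s) lack a '", reference,
            "' Ct and were excluded: ", paste(excluded, collapse = ", "))
  }
  rq <- rt %>%
    filter(target != reference) %>%
    inner_join(refs, by = "sample_id") %>%
    mutate(rq = relative_quantity(ct, reference_ct)) %>%
    left_join(mock, by = c("sample_id", "target")) %>%
    mutate(contaminated = !is.na(mock_ct) & (mock_ct - ct) < 5) %>%
    select(sample_id, condition, target, ct, reference_ct, rq, contaminated)

  levels <- unique(records$condition[!records$is_mock])
  summary <- NULL
  if (length(levels) == 2) {
    summary <- bind_rows(lapply(split(rq, rq$target), function(d) {
      a <- d$rq[d$condition == levels[1]]
      b <- d$rq[d$condition == levels[2]]
      if (length(a) < 2 || length(b) < 2) {
        stop("need >= 2 samples per condition for target ", d$target[1])
      }
      tt <- t_test_unpaired(a, b)
      tibble::tibble(
        target = d$target[1],
        condition_a = levels[1], condition_b = levels[2],
        mean_a = mean(a), sem_a = stats::sd(a) / sqrt(length(a)),
        mean_b = mean(b), sem_b = stats::sd(b) / sqrt(length(b)),
        n_a = length(a), n_b = length(b),
        t = tt$t, df = tt$df, p = tt$p
      )
    }))
  }
  list(rq = rq, summary = summary, excluded_samples = excluded)
}

#' Relative mitochondrial DNA content
#'
#' Identical arithmetic to [summarize_qpcr()] with the single-copy nuclear
#' amplicon as reference: `2^-(Ct_mtDNA - Ct_nuclear)` per sample, plus the
#' between-condition comparison.
#'
#' @param records Tibble `sample_id`, `condition`, `target`, `ct` holding
#'   the mitochondrial amplicon and the nuclear single-copy reference.
#' @param mito_target Name of the mitochondrial amplicon (e.g. "D-loop").
#' @param reference Name of the nuclear single-copy gene (default "NXN").
#' @return As [summarize_qpcr()], restricted to `mito_target`.
#' @export
mtdna_content <- function(records, mito_target, reference = "NXN") {
  records <- tibble::as_tibble(records)
  keep <- records$target %in% c(mito_target, reference)
  out <- summarize_qpcr(records[keep, , drop = FALSE], reference = reference)
  out$rq <- out$rq %>% filter(target == mito_target)
  if (!is.null(out$summary)) {
    out$summary <- out$summary %>% filter(target == mito_target)
  }
  out
}

#' Simulate a qPCR Ct table
#'
#' Ct values are drawn as `base_ct + effect + Normal(0, noise_sd^2)`, with
#' the treatment effect expressed as a ΔCt shift (`-1` cycle = twofold
#' up).  The reference target gets no effect.
#'
#' @param targets Character vector of target names (reference excluded).
#' @param delta_ct_shift Named numeric: per-target ΔCt shift applied in the
#'   second condition (negative = upregulated).
#' @param n_per_group Samples per condition.
#' @param conditions Two condition labels.
#' @param reference Reference target name.
#' @param base_ct Baseline Ct of every target and the reference.
#' @param noise_sd Ct measurement noise SD (cycles).
#' @param seed RNG seed.
#' @return Tibble `sample_id`, `condition`, `target`, `ct`.
#' @export
simulate_ct_table <- function(targets, delta_ct_shift, n_per_group = 6,
                              conditions = c("con", "ldl"),
                              reference = "RPL32", base_ct = 25,
                              noise_sd = 0.2, seed = 1) {
  stopifnot(length(conditions) == 2,
            all(targets %in% names(delta_ct_shift)))
  withr_seed(seed, {
    rows <- list()
    for (ci in 1:2) {
      for (r in seq_len(n_per_group)) {
        sid <- sprintf("%s_%d", conditions[ci], r)
        ct_ref <- base_ct + rnorm(1, 0, noise_sd)
        rows[[length(rows) + 1]] <- tibble::tibble(
          sample_id = sid, condition = conditions[ci],
          target = reference, ct = ct_ref
        )
        for (tg in targets) {
          shift <- if (ci == 2) delta_ct_shift[[tg]] else 0
          rows[[length(rows) + 1]] <- tibble::tibble(
            sample_id = sid, condition = conditions[ci],
            target = tg, ct = base_ct + shift + rnorm(1, 0, noise_sd)
          )
        }
      }
    }
    bind_rows(rows)
  })
}

#' Read a qPCR Ct table from TSV
#'
#' Expected columns: `sample_id`, `condition`, `target`, `ct`, optional
#' `is_mock`.
#'
#' @param path TSV file.
#' @return Tibble of Ct records.
#' @export
read_ct_table <- function(path) {
  tibble::as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}
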