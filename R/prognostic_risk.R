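# Univariate Cox screening of signature NES against overall survival.
# A signature with hazard ratio > 1 is a risk factor, < 1 protective;
# p <= alpha (Wald) marks it prognostic. A cell type whose prognostic
# signatures all agree in direction is a consistent factor.

#' Univariate Cox fit of survival on one signature's NES
#'
#' Proportional-hazards regression of overall survival on the per-sample NES
#' of a single signature (Efron tie handling). Degenerate inputs (constant
#' covariate, fewer than two events, non-convergence) yield an indeterminate
#' record with the reason, not an exception.
#'
#' @param nes_values Named numeric vector of NES, names are sample ids.
#' @param survival `data.frame` with columns `sample`, `time`, `event`.
#' @return List with `hazard_ratio` (exp of the fitted log-hazard per full
#'   NES unit), `p_value` (Wald), `n_samples`, `n_events`, `status`
#'   (`"ok"`/`"indeterminate"`) and `reason`.
#' @export
fit_cox_univariate <- function(nes_values, survival) {
  ids <- intersect(names(nes_values), survival$sample)
  if (!length(ids))
    stop("no overlapping samples between NES values and survival table")
  x <- as.numeric(nes_values[ids])
  surv <- survival[match(ids, survival$sample), , drop = FALSE]
  keep <- !is.na(x)
  x <- x[keep]
  surv <- surv[keep, , drop = FALSE]
  out <- list(hazard_ratio = NA_real_, p_value = NA_real_,
              n_samples = nrow(surv), n_events = sum(surv$event),
              status = "indeterminate", reason = NA_character_)
  if (nrow(surv) < 3L || sum(surv$event) < 2L) {
    out$reason <- "fewer than 2 events"
    return(out)
  }
  if (length(unique(x)) < 2L) {
    out$reason <- "constant covariate"
    return(out)
  }
  fit <- tryCatch(
    survival::coxph(survival::Surv(surv$time, surv$event) ~ x, ties = "efron"),
    warning = function(w) w, error = function(e) e
  )
  if (inherits(fit, "condition")) {
    out$reason <- conditionMessage(fit)
    return(out)
  }
  co <- summary(fit)$coefficients
  if (!is.finite(co[1, "coef"]) || !is.finite(co[1, "Pr(>|z|)"])) {
    out$reason <- "non-finite estimate"
    return(out)
  }
  out$hazard_ratio <- unname(exp(co[1, "coef"]))
  out$p_value <- unname(co[1, "Pr(>|z|)"])
  out$status <- "ok"
  out
}

#' Screen every signature's NES against overall survival
#'
#' One univariate Cox fit per signature. A signature is prognostic when its
#' Wald p-value is `<= alpha` (exactly alpha counts). Signatures with no
#' computable NES are reported as indeterminate with a warning. No multiple
#' -testing correction is applied by default; `fdr = TRUE` switches the
#' prognostic call to Benjamini-Hochberg adjusted p-values.
#'
#' @param nes A `nes_matrix` (or bare signatures x samples matrix).
#' @param survival Clinical `data.frame` (`sample`, `time`, `event`).
#' @param alpha Significance cut-off (default 0.05).
#' @param cohort_id Label stored with each record.
#' @param fdr Apply Benjamini-Hochberg before the alpha cut (default FALSE).
#' @return `data.frame` with one row per signature: `signature_id`,
#'   `cohort_id`, `hazard_ratio`, `p_value`, `n_samples`, `risk_label`
#'   (`risk`/`protective`/`indeterminate`) and `prognostic`.
#' @export
screen_signatures <- function(nes, survival, alpha = 0.05,
                              cohort_id = "cohort", fdr = FALSE) {
  scores <- nes_scores(nes)
  if (!length(intersect(colnames(scores), survival$sample)))
    stop("no overlap between NES samples and survival table")
  n_sig <- nrow(scores)
  recs <- vector("list", n_sig)
  n_skipped <- 0L
  for (i in seq_len(n_sig)) {
    v <- scores[i, ]
    if (all(is.na(v))) {
      n_skipped <- n_skipped + 1L
      recs[[i]] <- list(hazard_ratio = NA_real_, p_value = NA_real_,
                        n_samples = 0L, status = "indeterminate",
                        reason = "no computable NES")
    } else {
      recs[[i]] <- fit_cox_univariate(v, survival)
    }
  }
  if (n_skipped)
    warning(n_skipped, " signature(s) skipped: no computable NES")
  hr <- vapply(recs, `[[`, numeric(1), "hazard_ratio")
  p <- vapply(recs, `[[`, numeric(1), "p_value")
  status <- vapply(recs, `[[`, character(1), "status")
  label <- rep("indeterminate", n_sig)
  label[status == "ok" & !is.na(hr) & hr > 1] <- "risk"
  label[status == "ok" & !is.na(hr) & hr < 1] <- "protective"
  p_screen <- if (fdr) stats::p.adjust(p, method = "BH") else p
  prognostic <- status == "ok" & !is.na(p_screen) & p_screen <= alpha &
    label %in% c("risk", "protective")
  data.frame(
    signature_id = rownames(scores),
    cohort_id = cohort_id,
    hazard_ratio = hr,
    p_value = p,
    n_samples = vapply(recs, `[[`, numeric(1), "n_samples"),
    risk_label = label,
    prognostic = prognostic,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Cell-type consistency of prognostic risk directions
#'
#' Within each cohort a cell type is a consistent risk (or protective)
#' factor when all of its prognostic signatures carry that label; mixed
#' labels make it inconsistent, and no prognostic signatures at all give
#' direction `"none"`. Pooled rows (cohort `"pooled"`) additionally report
#' `cohort_count`: the number of cohorts in which the type is a consistent
#' factor of its direction.
#'
#' @param records Row-bound output of [screen_signatures()] across cohorts.
#' @param signatures The signature list the records refer to.
#' @return `data.frame` with columns `cell_type`, `cohort_id`, `direction`,
#'   `n_prognostic_signatures`, `cohort_count` (NA for per-cohort rows).
#' @export
consistency_by_cell_type <- function(records, signatures) {
  ids <- signature_ids(signatures)
  unknown <- setdiff(records$signature_id, ids)
  if (length(unknown))
    stop("records reference unknown signatures: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  type_of <- stats::setNames(signature_cell_types(signatures), ids)
  records$cell_type <- type_of[records$signature_id]
  out <- list()
  per_type_dirs <- list()
  for (ct in unique(records$cell_type)) {
    for (coh in unique(records$cohort_id)) {
      sub <- records[records$cell_type == ct & records$cohort_id == coh &
                       records$prognostic, , drop = FALSE]
      labs <- unique(sub$risk_label)
      direction <- if (nrow(sub) == 0L) "none"
        else if (length(labs) == 1L) labs
        else "inconsistent"
      out[[length(out) + 1L]] <- data.frame(
        cell_type = ct, cohort_id = coh, direction = direction,
        n_prognostic_signatures = nrow(sub), cohort_count = NA_integer_,
        stringsAsFactors = FALSE)
      per_type_dirs[[ct]] <- c(per_type_dirs[[ct]], direction)
    }
    dirs <- per_type_dirs[[ct]]
    n_risk <- sum(dirs == "risk")
    n_prot <- sum(dirs == "protective")
    pooled_dir <- if (n_risk > 0 && n_prot > 0) "inconsistent"
      else if (n_risk > 0) "risk"
      else if (n_prot > 0) "protective"
      else if (any(dirs == "inconsistent")) "inconsistent"
      else "none"
    n_prog_total <- sum(records$prognostic[records$cell_type == ct])
    out[[length(out) + 1L]] <- data.frame(
      cell_type = ct, cohort_id = "pooled", direction = pooled_dir,
      n_prognostic_signatures = n_prog_total,
      cohort_count = max(n_risk, n_prot),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
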