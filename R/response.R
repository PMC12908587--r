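# Responder classification and baseline balance checks.

#' Classify exercise-training response from body-composition change
#'
#' A subject is a responder when the change in fat-free mass exceeds the
#' change in fat mass: `score = (FFM_post - FFM_pre) - (FM_post - FM_pre)`
#' and `responder = score > 0` (strictly; a zero score is a non-responder).
#' Subjects missing a post measurement are excluded with a warning.
#'
#' @param cohort Data frame with `subject_id`, `ffm_pre`, `ffm_post`,
#'   `fm_pre`, `fm_post`.
#' @return Data frame of class `gf_response`: `subject_id`, `delta_ffm`,
#'   `delta_fm`, `score` (kg), `responder` (logical), with group counts in
#'   the `"counts"` attribute.
#' @export
classify_response <- function(cohort) {
  need <- c("subject_id", "ffm_pre", "ffm_post", "fm_pre", "fm_post")
  if (!all(need %in% names(cohort))) {
    stop("cohort needs columns: ", paste(need, collapse = ", "))
  }
  complete <- stats::complete.cases(cohort[, need[-1L]])
  if (any(!complete)) {
    warning(sprintf("excluding %d subject(s) with missing measurements: %s",
                    sum(!complete),
                    paste(cohort$subject_id[!complete], collapse = ", ")))
  }
  cohort <- cohort[complete, , drop = FALSE]
  delta_ffm <- cohort$ffm_post - cohort$ffm_pre
  delta_fm <- cohort$fm_post - cohort$fm_pre
  score <- delta_ffm - delta_fm
  out <- data.frame(subject_id = cohort$subject_id,
                    delta_ffm = delta_ffm, delta_fm = delta_fm,
                    score = score, responder = score > 0,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- c(responder = sum(out$responder),
                           non_responder = sum(!out$responder))
  class(out) <- c("gf_response", "data.frame")
  out
}

#' Baseline balance of response groups
#'
#' Tests for confounding between responders and non-responders at
#' baseline: Fisher's exact test on the sex distribution and exact
#' Wilcoxon rank-sum tests on age, pre-training BMI, fat mass, and
#' fat-free mass, with Benjamini-Hochberg q-values across the family of
#' five tests. The groups are declared balanced when all q > 0.05.
#'
#' @param cohort Data frame with `subject_id`, `sex` (F/M), `age`,
#'   `bmi_pre`, `fm_pre`, `ffm_pre`.
#' @param labels Output of [classify_response()] (or a data frame with
#'   `subject_id` and `responder`).
#' @return Data frame (`variable`, `test`, `statistic`, `p`, `q`) with a
#'   logical `"balanced"` attribute.
#' @export
baseline_balance <- function(cohort, labels) {
  merged <- merge(cohort, labels[, c("subject_id", "responder")],
                  by = "subject_id")
  g1 <- merged[merged$responder, , drop = FALSE]
  g0 <- merged[!merged$responder, , drop = FALSE]
  if (nrow(g1) < 2L || nrow(g0) < 2L) {
    stop("each response group must contain at least 2 subjects")
  }
  sex_tab <- table(factor(merged$sex, levels = c("F", "M")),
                   factor(merged$responder, levels = c(TRUE, FALSE)))
  fisher <- fisher_exact_2x2(sex_tab)
  vars <- c("age", "bmi_pre", "fm_pre", "ffm_pre")
  missing_vars <- setdiff(vars, names(merged))
  if (length(missing_vars) > 0L) {
    stop("cohort lacks columns: ", paste(missing_vars, collapse = ", "))
  }
  rows <- lapply(vars, function(v) {
    w <- wilcoxon_rank_sum(g1[[v]], g0[[v]])
    data.frame(variable = v, test = "wilcoxon_rank_sum",
               statistic = w$statistic, p = w$p.value)
  })
  out <- rbind(data.frame(variable = "sex", test = "fisher_exact",
                          statistic = NA_real_, p = fisher$p.value),
               do.call(rbind, rows))
  out$q <- bh_fdr(out$p)
  attr(out, "balanced") <- all(out$q > 0.05)
  out
}

#' Paired pre/post change test within each response group
#'
#' Exact Wilcoxon signed-rank test of the post-minus-pre differences
#' within each group. Groups whose differences are all zero are flagged
#' degenerate and reported with p = 1.
#'
#' @param pre,post Paired measurements (equal length).
#' @param by_group Factor/logical splitting subjects into groups.
#' @return Data frame: `group`, `n`, `statistic`, `p`, `degenerate`.
#' @export
paired_change_test <- function(pre, post, by_group) {
  if (length(pre) != length(post) || length(pre) != length(by_group)) {
    stop("pre, post and by_group must be aligned")
  }
  groups <- split(seq_along(pre), by_group)
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    if (length(idx) < 5L) stop("group '", g, "' has fewer than 5 pairs")
    d <- post[idx] - pre[idx]
    if (all(d == 0)) {
      return(data.frame(group = g, n = length(idx), statistic = NA_real_,
                        p = 1, degenerate = TRUE))
    }
    w <- wilcoxon_signed_rank(d)
    data.frame(group = g, n = length(idx), statistic = w$statistic,
               p = w$p.value, degenerate = FALSE)
  })
  do.call(rbind, rows)
}
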