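# Logistic-normal synthetic microbiome compositions with planted effects.

softmax <- function(l) {
  e <- exp(l - max(l))
  e / sum(e)
}

# Solve for the temperature T such that shannon(softmax(l / T)) equals the
# target; H is monotone increasing in T (T -> 0 concentrates, T -> Inf is
# uniform). Root-found on log T.
solve_temperature <- function(l, target) {
  f <- function(logt) shannon(softmax(l / exp(logt))) - target
  stats::uniroot(f, lower = -4, upper = 4, extendInt = "yes",
                 tol = 1e-10)$root
}

#' Generate pre/post species relative-abundance tables with planted effects
#'
#' Per-sample compositions follow a logistic-normal model: a species
#' log-profile (spread `sigma_species`) plus subject-level offsets (spread
#' `sigma_subject`, multiplied by `responder_dispersion_scale` for
#' responders, which plants the beta-dispersion difference) plus
#' sample-level noise, pushed through a softmax. Planted predictor species
#' are shifted by `predictor_log2_effect` log2 units in responders'
#' baseline samples. Alpha diversity is controlled exactly: per-sample
#' Shannon targets are drawn through a Gaussian copula so that baseline
#' Shannon couples to the RMR-adaptation latent at `rho_shannon0_rmr` and
#' the pre-to-post Shannon change couples to the TDEE-adaptation latent at
#' `rho_shannon_tdee`, then each composition is tempered (`p ~ p^(1/T)`)
#' to hit its target. Abundances below the detection limit are zeroed and
#' the composition renormalized, emulating a classifier's detection floor.
#'
#' @param config A [synth_config()].
#' @param cohort,truth Output of [generate_cohort()].
#' @param tree Phylogeny from [generate_tree()] (leaf set defines the
#'   species universe; must have `config$n_species` tips).
#' @param seed Optional seed override (defaults to a stream derived from
#'   `config$seed`).
#' @param sigma_species,sigma_subject,sigma_sample Log-scale spreads of
#'   the species profile, subject offsets, and sample noise.
#' @param h0_mean,h0_sd Baseline Shannon target distribution (nats).
#' @param dh_mean,dh_sd Shannon-change target distribution.
#' @param detection_limit Relative abundance below which a species is
#'   unobserved (default 1e-5).
#' @return List with `table` (2n samples x species matrix, rows named
#'   `"S<id>_pre"` / `"S<id>_post"`, rows summing to 1), `metadata`
#'   (sample_id, subject_id, timepoint, responder), `predictor_species`,
#'   and `realized` (the realized planted correlations).
#' @export
generate_abundance <- function(config, cohort, truth, tree, seed = NULL,
                               sigma_species = 2.0, sigma_subject = 0.4,
                               sigma_sample = 0.22,
                               h0_mean = 3.6, h0_sd = 0.35,
                               dh_mean = 0.1, dh_sd = 0.3,
                               detection_limit = 1e-5) {
  stopifnot(inherits(config, "gf_synth_config"))
  S <- config$n_species
  if (length(tree$tip.label) != S) {
    stop("tree leaf count does not match n_species")
  }
  sp <- sort(tree$tip.label)
  n <- nrow(cohort)
  if (is.null(seed)) seed <- derive_seed(config$seed, 3L)
  with_seed(seed, {
    mu <- stats::rnorm(S, 0, sigma_species)
    # predictor species: moderately abundant (between the 50th and 90th
    # base-profile percentiles) so they survive the prevalence filter
    eligible <- which(mu > stats::quantile(mu, 0.5) &
                        mu < stats::quantile(mu, 0.9))
    if (length(eligible) < config$n_predictor_species) {
      eligible <- order(mu, decreasing = TRUE)[seq_len(max(
        config$n_predictor_species, ceiling(S / 3)))]
    }
    predictor_idx <- sort(sample(eligible, config$n_predictor_species))
    responder <- truth$responder_true

    # Gaussian-copula Shannon targets coupled to the adaptation latents
    rho0 <- config$rho_shannon0_rmr
    rho1 <- config$rho_shannon_tdee
    z_h0 <- rho0 * truth$z_rmr + sqrt(1 - rho0^2) * stats::rnorm(n)
    z_dh <- rho1 * truth$z_tdee + sqrt(1 - rho1^2) * stats::rnorm(n)
    h_max <- log(S) - 0.1
    h0 <- pmin(pmax(h0_mean + h0_sd * z_h0, 1), h_max)
    h1 <- pmin(pmax(h0 + dh_mean + dh_sd * z_dh, 1), h_max)

    offsets <- matrix(stats::rnorm(n * S, 0, sigma_subject), nrow = n)
    offsets[responder, ] <- offsets[responder, ] * config$responder_dispersion_scale

    make_sample <- function(i, timepoint) {
      l <- mu + offsets[i, ] + stats::rnorm(S, 0, sigma_sample)
      if (timepoint == "pre" && responder[i]) {
        l[predictor_idx] <- l[predictor_idx] +
          log(2) * config$predictor_log2_effect
      }
      target <- if (timepoint == "pre") h0[i] else h1[i]
      # degeneracy is judged on the raw logistic-normal composition: the
      # diversity tempering below would silently absorb any planted spike
      if (any(softmax(l) > 0.99)) {
        stop("planted effect degenerates the composition ",
             "(a species exceeds 0.99 relative abundance)")
      }
      p <- softmax(l / exp(solve_temperature(l, target)))
      p[p < detection_limit] <- 0
      p <- p / sum(p)
      if (any(p > 0.99)) {
        stop("planted effect degenerates the composition ",
             "(a species exceeds 0.99 relative abundance)")
      }
      p
    }
    rows <- list()
    meta <- list()
    for (tp in c("pre", "post")) {
      for (i in seq_len(n)) {
        sid <- paste0(cohort$subject_id[i], "_", tp)
        rows[[sid]] <- make_sample(i, tp)
        meta[[sid]] <- data.frame(sample_id = sid,
                                  subject_id = cohort$subject_id[i],
                                  timepoint = tp,
                                  responder = responder[i],
                                  stringsAsFactors = FALSE)
      }
    }
    table <- do.call(rbind, rows)
    colnames(table) <- sp
    metadata <- do.call(rbind, meta)
    rownames(metadata) <- NULL

    h_pre <- apply(table[metadata$timepoint == "pre", , drop = FALSE],
                   1L, shannon)
    h_post <- apply(table[metadata$timepoint == "post", , drop = FALSE],
                    1L, shannon)
    realized <- c(
      rho_shannon_tdee = stats::cor(h_post - h_pre,
                                    truth$adaptation_tdee_true),
      rho_shannon0_rmr = stats::cor(h_pre, truth$adaptation_rmr_true))
    list(table = table, metadata = metadata,
         predictor_species = sp[predictor_idx], realized = realized)
  })
}
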