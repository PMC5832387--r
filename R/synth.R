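# Synthetic data generator. Emulates the statistical structure of real
# drug--side-effect data: a very sparse binary bipartite matrix with
# heavy-tailed degree distributions, a three-level anatomical hierarchy
# with uneven category sizes, and correlated molecular-descriptor-like
# features that carry an organ-coherent signal of configurable strength.
#
# Generative model for the association of drug i with side effect s:
#   P(y_is = 1) = logistic(mu + a_i + b_s + beta * <x_i, w_organ(s)>)
# with drug latents x_i ~ N(0, I_d), organ weights w_o ~ N(0, I_d)/sqrt(d),
# drug offsets a_i ~ N(0, sigma_a^2), side-effect offsets b_s ~ N(0,
# sigma_b^2). The intercept mu is calibrated by bisection so the expected
# matrix density matches the configured target. Features are a random
# linear read-out of the latents plus Gaussian noise, so anatomical
# aggregation of labels is learnable from features while any random
# regrouping of side effects mixes incoherent organ signals.

#' Configuration for the synthetic data generator
#'
#' Defaults emulate a desk-scale version of real drug--event data: 200
#' drugs by 400 side effects at 2% density (98% zeros), a 61-organ /
#' 30-sub-system / 12-system hierarchy, and 387 correlated descriptor
#' features driven by 10 latent dimensions.
#'
#' @param n_drugs,n_se numbers of drugs and side effects.
#' @param n_systems,n_subsystems,n_organs hierarchy sizes (systems <=
#'   sub-systems <= organs <= side effects).
#' @param latent_dim dimension of the drug latent vectors.
#' @param n_features number of observed descriptor columns.
#' @param beta organ-signal strength on the logit scale; 0 removes any
#'   relation between features and labels.
#' @param sigma_a,sigma_b standard deviations of per-drug and
#'   per-side-effect logit offsets; these create the heavy-tailed degree
#'   distributions seen in real data.
#' @param target_density desired fraction of ones in the association
#'   matrix.
#' @param feature_noise_sd standard deviation of the feature noise.
#' @param seed integer seed consumed by [generate_dataset()].
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_drugs = 200L, n_se = 400L,
                         n_systems = 12L, n_subsystems = 30L, n_organs = 61L,
                         latent_dim = 10L, n_features = 387L,
                         beta = 2, sigma_a = 1, sigma_b = 1,
                         target_density = 0.02, feature_noise_sd = 0.5,
                         seed = NULL) {
  cfg <- list(n_drugs = as.integer(n_drugs), n_se = as.integer(n_se),
              n_systems = as.integer(n_systems),
              n_subsystems = as.integer(n_subsystems),
              n_organs = as.integer(n_organs),
              latent_dim = as.integer(latent_dim),
              n_features = as.integer(n_features),
              beta = beta, sigma_a = sigma_a, sigma_b = sigma_b,
              target_density = target_density,
              feature_noise_sd = feature_noise_sd, seed = seed)
  with(cfg, {
    if (!(n_organs >= n_subsystems && n_subsystems >= n_systems &&
          n_systems >= 1L)) {
      stop("hierarchy sizes must satisfy n_organs >= n_subsystems >= n_systems >= 1")
    }
    if (n_se < n_organs) stop("need n_se >= n_organs")
    if (beta < 0 || sigma_a < 0 || sigma_b < 0 || feature_noise_sd < 0) {
      stop("beta and standard deviations must be non-negative")
    }
    if (target_density <= 0 || target_density >= 1) {
      stop("target_density must be in (0, 1)")
    }
  })
  structure(cfg, class = "synth_config")
}

# sizes of `k` groups over `n` items, each >= 1, drawn Dirichlet(1)-
# multinomial so group sizes are uneven
partition_sizes <- function(n, k) {
  if (n < k) stop("cannot partition ", n, " items into ", k, " non-empty groups")
  if (n == k) return(rep(1L, k))
  p <- stats::rgamma(k, shape = 1)
  1L + as.integer(stats::rmultinom(1L, n - k, p / sum(p)))
}

pad_id <- function(prefix, n) {
  sprintf(paste0(prefix, "_%0", nchar(as.character(n)), "d"), seq_len(n))
}

#' Generate a random three-level anatomical hierarchy
#'
#' Side effects are partitioned among organs, organs among sub-systems
#' and sub-systems among systems. Category sizes are drawn from a
#' symmetric Dirichlet-multinomial (concentration 1) so sizes are uneven,
#' with every category receiving at least one member.
#'
#' Uses the current RNG state; seed the generator (or call through
#' [generate_dataset()]) for reproducibility.
#'
#' @param config a `synth_config`.
#' @return An `anatomical_schema` with no MISC terms.
#' @export
generate_hierarchy <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  systems <- pad_id("system", config$n_systems)
  subsystems <- pad_id("subsys", config$n_subsystems)
  organs <- pad_id("organ", config$n_organs)
  ses <- pad_id("se", config$n_se)

  sub_to_sys <- rep(systems, partition_sizes(config$n_subsystems, config$n_systems))
  org_to_sub <- rep(subsystems, partition_sizes(config$n_organs, config$n_subsystems))
  se_to_org <- rep(organs, partition_sizes(config$n_se, config$n_organs))

  org_sub <- stats::setNames(org_to_sub, organs)
  sub_sys <- stats::setNames(sub_to_sys, subsystems)
  anatomical_schema(data.frame(
    side_effect = ses,
    organ = se_to_org,
    sub_system = unname(org_sub[se_to_org]),
    system = unname(sub_sys[org_sub[se_to_org]]),
    stringsAsFactors = FALSE
  ))
}

# find mu by bisection so that mean(plogis(mu + logits)) == target
calibrate_intercept <- function(logits, target, tol = 1e-4, max_iter = 100L) {
  lo <- -30; hi <- 30
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    dens <- mean(stats::plogis(mid + logits))
    if (abs(dens - target) < tol) return(mid)
    if (dens > target) hi <- mid else lo <- mid
  }
  stop("density calibration did not converge in ", max_iter, " iterations")
}

#' Generate a sparse binary drug x side-effect matrix with planted
#' organ-coherent signal
#'
#' See the generative model in the package vignette: per-cell Bernoulli
#' draws with logit `mu + a_i + b_s + beta * <x_i, w_organ(s)>`, the
#' intercept calibrated so expected density equals
#' `config$target_density`.
#'
#' @param schema hierarchy from [generate_hierarchy()].
#' @param config a `synth_config`.
#' @return list with `associations` (binary matrix, side-effect level)
#'   and `truth` (latents `x`, organ weights `w`, offsets `a`, `b`,
#'   `beta`, calibrated `mu`).
#' @export
generate_associations <- function(schema, config) {
  stopifnot(inherits(schema, "anatomical_schema"),
            inherits(config, "synth_config"))
  d <- config$latent_dim
  terms <- schema$terms
  organs <- sort(unique(terms$organ))
  drugs <- pad_id("drug", config$n_drugs)

  x <- matrix(stats::rnorm(config$n_drugs * d), config$n_drugs, d,
              dimnames = list(drugs, NULL))
  w <- matrix(stats::rnorm(length(organs) * d) / sqrt(d), length(organs), d,
              dimnames = list(organs, NULL))
  a <- stats::rnorm(config$n_drugs, sd = config$sigma_a)
  b <- stats::rnorm(config$n_se, sd = config$sigma_b)

  organ_of_se <- terms$organ[match(terms$side_effect, terms$side_effect)]
  se_ids <- terms$side_effect
  signal <- x %*% t(w)                       # drugs x organs
  logits <- outer(a, b, `+`) +
    config$beta * signal[, match(terms$organ, organs), drop = FALSE]
  colnames(logits) <- se_ids

  mu <- calibrate_intercept(logits, config$target_density)
  p <- stats::plogis(mu + logits)
  y <- matrix(stats::rbinom(length(p), 1L, p), nrow(p), ncol(p),
              dimnames = list(drugs, se_ids))
  list(
    associations = association_matrix(y, level = "side_effect"),
    truth = list(x = x, w = w, a = a, b = b,
                 beta = config$beta, mu = mu)
  )
}

#' Generate correlated descriptor features from drug latents
#'
#' Features are a fixed random linear read-out of the drug latents plus
#' Gaussian noise — low-rank-plus-noise, as real descriptor tables are —
#' so principal components recover the latent space.
#'
#' @param truth truth list from [generate_associations()] (needs `x`).
#' @param config a `synth_config`.
#' @param loading optional fixed loading matrix (latent_dim x n_features);
#'   by default drawn `N(0, 1)/sqrt(latent_dim)`.
#' @return numeric feature matrix (drugs x n_features).
#' @export
generate_features <- function(truth, config, loading = NULL) {
  stopifnot(inherits(config, "synth_config"))
  d <- config$latent_dim
  if (is.null(loading)) {
    loading <- matrix(stats::rnorm(d * config$n_features) / sqrt(d),
                      d, config$n_features)
  }
  stopifnot(nrow(loading) == d)
  noise <- matrix(stats::rnorm(nrow(truth$x) * ncol(loading),
                               sd = config$feature_noise_sd),
                  nrow(truth$x), ncol(loading))
  feats <- truth$x %*% loading + noise
  dimnames(feats) <- list(rownames(truth$x), pad_id("feat", ncol(loading)))
  feats
}

#' Generate a complete synthetic dataset
#'
#' Composes [generate_hierarchy()], [generate_associations()] and
#' [generate_features()] under a single seed; the same seed reproduces
#' the dataset bit for bit.
#'
#' @param config a `synth_config`; its `seed` (if non-NULL) seeds the RNG.
#' @return An object of class `synth_dataset`: list with `schema`,
#'   `associations`, `features`, `truth` and `config`.
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  schema <- generate_hierarchy(config)
  assoc <- generate_associations(schema, config)
  features <- generate_features(assoc$truth, config)
  structure(
    list(schema = schema, associations = assoc$associations,
         features = features, truth = assoc$truth, config = config),
    class = "synth_dataset"
  )
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("Synthetic drug--side-effect dataset: %d drugs x %d side effects\n",
              nrow(x$associations), ncol(x$associations)))
  cat(sprintf("  density %.3f | hierarchy %d organs / %d sub-systems / %d systems\n",
              mean(x$associations),
              x$config$n_organs, x$config$n_subsystems, x$config$n_systems))
  cat(sprintf("  features: %d columns, signal strength beta = %.2f\n",
              ncol(x$features), x$config$beta))
  invisible(x)
}

#' Write a synthetic dataset as plain-text files
#'
#' Writes `schema.tsv`, `associations.csv` (triplet form
#' `drug,side_effect,value`) and `features.csv` into a directory.
#'
#' @param dataset a `synth_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synth_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(dataset$schema$terms[c("side_effect", "organ",
                                            "sub_system", "system")],
                     file.path(dir, "schema.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  idx <- which(dataset$associations == 1L, arr.ind = TRUE)
  trip <- data.frame(drug = rownames(dataset$associations)[idx[, 1]],
                     side_effect = colnames(dataset$associations)[idx[, 2]],
                     value = 1L)
  trip <- trip[order(trip$drug, trip$side_effect), ]
  utils::write.csv(trip, file.path(dir, "associations.csv"), row.names = FALSE)
  utils::write.csv(data.frame(drug = rownames(dataset$features),
                              dataset$features, check.names = FALSE),
                   file.path(dir, "features.csv"), row.names = FALSE)
  invisible(dir)
}
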