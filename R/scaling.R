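#' Reconcile the modified-habitat affinity and sensitivity parameters
#'
#' The two parameterisations of the matrix quality are linked by
#' \eqn{h_2 = h_1 (1 - \sigma)^{1/z}}. Given either one the other is
#' derived; given both they must agree to within \code{tol}.
#'
#' @param z SAR exponent.
#' @param h1 Native-habitat affinity (default 1).
#' @param h2 Modified-habitat affinity, or \code{NULL} to derive from
#'   \code{sigma}.
#' @param sigma Plot-scale sensitivity, or \code{NULL} to derive from
#'   \code{h2}.
#' @param tol Consistency tolerance when both are supplied.
#' @return List with elements \code{h1}, \code{h2}, \code{sigma}.
#' @export
resolve_matrix_params <- function(z, h1 = 1, h2 = NULL, sigma = NULL,
                                  tol = 1e-6) {
  if (is.null(h2) && is.null(sigma)) {
    stop("supply `h2` or `sigma` (or both)", call. = FALSE)
  }
  if (is.null(h2)) {
    h2 <- h1 * affinity_from_sensitivity(sigma, z)
  } else if (is.null(sigma)) {
    sigma <- sensitivity_from_affinity(h2 / h1, z)
  } else {
    implied <- h1 * affinity_from_sensitivity(sigma, z)
    if (abs(implied - h2) > tol) {
      stop(sprintf(
        "`h2` (%.6g) and `sigma` (%.6g) are inconsistent: sigma implies h2 = %.6g",
        h2, sigma, implied
      ), call. = FALSE)
    }
  }
  list(h1 = h1, h2 = h2, sigma = sigma)
}

# per-window extinction fractions for one model on one window grid
window_extinctions <- function(grid, model, z, h1, h2, sigma) {
  A <- grid$window_cells
  a <- grid$modified_fractions * A
  switch(model,
    classic = classic_extinction(a, A, z),
    countryside = countryside_extinction(a, A, h1 = h1, h2 = h2, z = z),
    linear = linear_extinction(a, A, sigma = sigma),
    stop(sprintf("unknown model '%s'", model), call. = FALSE)
  )
}

#' Mean extinction fraction at one sampling grain
#'
#' Tiles the landscape into windows of edge \code{omega}, applies the
#' chosen extinction model to each window's converted area (with the
#' window area \eqn{\Omega^2} as the total area \eqn{A}), and averages:
#' \deqn{\bar\varepsilon(\Omega) = \sum_k \varepsilon(a_k^\Omega) / N(\Omega).}
#'
#' @param landscape A \code{sar_landscape}.
#' @param omega Window edge length; must divide the lattice side.
#' @param model One of \code{"classic"}, \code{"countryside"},
#'   \code{"linear"}.
#' @param z SAR exponent (classic and countryside models).
#' @param h1,h2,sigma Matrix-quality parameters; supply \code{h2} or
#'   \code{sigma}, see [resolve_matrix_params()].
#' @return List with \code{mean_epsilon}, \code{sd_epsilon} (population
#'   standard deviation over windows) and \code{epsilon} (the per-window
#'   values).
#' @export
mean_extinction_at_scale <- function(landscape, omega, model, z = 0.2,
                                     h1 = 1, h2 = NULL, sigma = NULL) {
  model <- match.arg(model, c("classic", "countryside", "linear"))
  pars <- if (model == "classic") {
    list(h1 = 1, h2 = 0, sigma = 1)
  } else {
    resolve_matrix_params(z, h1, h2, sigma)
  }
  grid <- partition_windows(landscape, omega)
  eps <- window_extinctions(grid, model, z, pars$h1, pars$h2, pars$sigma)
  list(
    mean_epsilon = mean(eps),
    sd_epsilon = sd_pop(eps),
    epsilon = eps
  )
}

# population standard deviation (denominator n); exactly 0 for one value
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(max(mean((x - m)^2), 0))
}

#' Configuration for a scaling experiment
#'
#' Bundles and validates the parameters of a replicate scaling experiment:
#' landscape geometry, SAR parameters, replicate count and base seed.
#' The default values are the study conditions used throughout the
#' package's worked analyses: a 64 x 64 lattice with 10\% native habitat
#' left (90\% converted), \code{z = 0.2}, and a modified-habitat affinity
#' \code{h2 = 0.01} (the permanent-cropland affinity corresponding to a
#' plot-scale sensitivity of about 0.6).
#'
#' @param side Lattice edge (cells).
#' @param native_fraction Proportion of native habitat.
#' @param n_fragments \code{NULL} for spatially random landscapes, or a
#'   fragment count for clustered landscapes.
#' @param z SAR exponent.
#' @param h1 Native-habitat affinity.
#' @param h2,sigma Modified-habitat affinity / sensitivity (either or
#'   both; reconciled via the affinity relation).
#' @param n_replicates Number of replicate landscapes.
#' @param base_seed Integer seed from which per-replicate seeds are drawn.
#' @param models Subset of \code{c("classic", "countryside", "linear")}.
#' @param sd_mode \code{"pooled"} (sd over all windows pooled across
#'   replicates) or \code{"replicate"} (sd of per-replicate means).
#' @return A validated list of class \code{scaling_config}.
#' @export
scaling_config <- function(side = 64, native_fraction = 0.10,
                           n_fragments = NULL, z = 0.2, h1 = 1,
                           h2 = 0.01, sigma = NULL, n_replicates = 100,
                           base_seed = 1,
                           models = c("classic", "countryside", "linear"),
                           sd_mode = c("pooled", "replicate")) {
  models <- match.arg(models, several.ok = TRUE)
  sd_mode <- match.arg(sd_mode)
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  pars <- resolve_matrix_params(z, h1, h2, sigma)
  structure(
    list(
      side = side, native_fraction = native_fraction,
      n_fragments = n_fragments, z = z,
      h1 = pars$h1, h2 = pars$h2, sigma = pars$sigma,
      n_replicates = as.integer(n_replicates),
      base_seed = as.integer(base_seed),
      models = models, sd_mode = sd_mode
    ),
    class = "scaling_config"
  )
}

#' Run a replicate scaling experiment
#'
#' Generates \code{n_replicates} landscapes, computes the mean per-window
#' extinction fraction at every window size in the doubling sequence for
#' each requested model, and averages the curves across replicates.
#' Replicate seeds are derived deterministically from \code{base_seed}, so
#' the whole experiment is reproducible.
#'
#' @param config A [scaling_config()].
#' @return A data frame of class \code{scaling_curve} with columns
#'   \code{model}, \code{omega}, \code{window_area}, \code{mean_epsilon},
#'   \code{sd_epsilon} and \code{n_windows} (total windows across
#'   replicates). The configuration is attached as attribute
#'   \code{"config"}.
#' @examples
#' cfg <- scaling_config(side = 16, n_replicates = 5, base_seed = 42)
#' head(run_scaling_experiment(cfg))
#' @export
run_scaling_experiment <- function(config) {
  stopifnot(inherits(config, "scaling_config"))
  sizes <- window_sizes(config$side)
  models <- config$models
  nm <- length(models)
  ns <- length(sizes)
  s1 <- s2 <- matrix(0, nm, ns, dimnames = list(models, sizes))
  n <- matrix(0L, nm, ns)
  rep_means <- array(NA_real_, c(nm, ns, config$n_replicates))
  set.seed(config$base_seed)
  rep_seeds <- sample.int(.Machine$integer.max, config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    L <- tryCatch(
      {
        if (is.null(config$n_fragments)) {
          generate_random_landscape(config$side, config$native_fraction,
            seed = rep_seeds[r], audit_fragments = FALSE
          )
        } else {
          generate_clustered_landscape(config$side, config$native_fraction,
            config$n_fragments,
            seed = rep_seeds[r]
          )
        }
      },
      error = function(e) {
        stop(sprintf("replicate %d: %s", r, conditionMessage(e)), call. = FALSE)
      }
    )
    for (j in seq_along(sizes)) {
      grid <- partition_windows(L, sizes[j])
      for (i in seq_len(nm)) {
        eps <- window_extinctions(
          grid, models[i], config$z, config$h1, config$h2, config$sigma
        )
        s1[i, j] <- s1[i, j] + sum(eps)
        s2[i, j] <- s2[i, j] + sum(eps^2)
        n[i, j] <- n[i, j] + length(eps)
        rep_means[i, j, r] <- mean(eps)
      }
    }
  }
  mean_eps <- s1 / n
  sd_eps <- if (config$sd_mode == "pooled") {
    sqrt(pmax(s2 / n - mean_eps^2, 0))
  } else {
    apply(rep_means, c(1, 2), stats::sd)
  }
  out <- data.frame(
    model = rep(models, times = ns),
    omega = rep(sizes, each = nm),
    window_area = rep(sizes^2, each = nm),
    mean_epsilon = as.vector(mean_eps),
    sd_epsilon = as.vector(sd_eps),
    n_windows = as.vector(n),
    stringsAsFactors = FALSE
  )
  out <- out[order(match(out$model, models), out$omega), ]
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("scaling_curve", "data.frame")
  out
}

#' Summarise how the spread of window-level extinctions decays with grain
#'
#' For each model, reports the standard deviation of per-window extinction
#' fractions at every sampling grain, checks that it is non-increasing in
#' window size, and orders the models from fastest to slowest decay of the
#' spread relative to its grain-1 value.
#'
#' @param curves A \code{scaling_curve} (from [run_scaling_experiment()]).
#' @param tol Slack allowed when checking monotone decline.
#' @return List of class \code{variance_decay} with elements \code{table}
#'   (model, omega, sd_epsilon, relative sd), \code{monotone} (named
#'   logical per model) and \code{ordering} (model names, fastest decay
#'   first).
#' @export
variance_decay_summary <- function(curves, tol = 1e-9) {
  stopifnot(inherits(curves, "scaling_curve"))
  models <- unique(curves$model)
  tab <- curves[order(match(curves$model, models), curves$omega),
    c("model", "omega", "sd_epsilon"),
    drop = FALSE
  ]
  tab$rel_sd <- NA_real_
  monotone <- logical(length(models))
  names(monotone) <- models
  decay <- numeric(length(models))
  names(decay) <- models
  for (m in models) {
    i <- tab$model == m
    sds <- tab$sd_epsilon[i]
    monotone[m] <- all(diff(sds) <= tol)
    rel <- if (sds[1] > 0) sds / sds[1] else rep(0, length(sds))
    tab$rel_sd[i] <- rel
    decay[m] <- mean(rel) # small mean relative sd = fast decay
  }
  structure(
    list(
      table = tab,
      monotone = monotone,
      ordering = names(sort(decay))
    ),
    class = "variance_decay"
  )
}

#' @export
print.variance_decay <- function(x, ...) {
  cat("Window-level sd of extinction fraction by sampling grain\n")
  print(x$table, row.names = FALSE)
  cat(
    "\nsd non-increasing in window size:",
    paste(sprintf("%s=%s", names(x$monotone), x$monotone), collapse = ", "),
    "\nfastest to slowest decay:", paste(x$ordering, collapse = " < "), "\n"
  )
  invisible(x)
}

#' Plot a scaling curve
#'
#' Mean extinction fraction against the natural log of the sampling-window
#' area, one line per model, with vertical bars of one standard deviation.
#'
#' @param x A \code{scaling_curve}.
#' @param ... Passed to [graphics::matplot()].
#' @return \code{x}, invisibly.
#' @export
plot.scaling_curve <- function(x, ...) {
  models <- unique(x$model)
  la <- log(unique(x$window_area))
  m <- sapply(models, function(mm) x$mean_epsilon[x$model == mm])
  s <- sapply(models, function(mm) x$sd_epsilon[x$model == mm])
  graphics::matplot(la, m,
    type = "b", pch = 19, lty = 1,
    xlab = "ln(window area) [cells]",
    ylab = "proportion of species extinctions",
    ylim = range(c(m - s, m + s)), ...
  )
  for (i in seq_along(models)) {
    graphics::arrows(la, m[, i] - s[, i], la, m[, i] + s[, i],
      angle = 90, code = 3, length = 0.03, col = i
    )
  }
  graphics::legend("topright", legend = models, col = seq_along(models), lty = 1)
  invisible(x)
}
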