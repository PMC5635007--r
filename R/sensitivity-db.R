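#' Closed vocabularies of the sensitivity database
#'
#' Factor levels used to classify each native-vs-modified richness
#' comparison: taxon, biome, and the land-use class of the modified
#' habitat.
#' @name vocabularies
#' @keywords internal
NULL

taxon_levels <- c("bird", "plant")
region_levels <- c("tropical", "temperate")
land_use_levels <- c(
  "annual_crops", "managed_forest", "permanent_crops", "pastures", "urban"
)

#' Load a sensitivity database from CSV
#'
#' Reads a table of paired native/modified species-richness comparisons.
#' The file must have a header naming at least \code{study_id},
#' \code{taxon}, \code{region}, \code{land_use}, and either a richness
#' pair (\code{s_native}, \code{s_modified}) or a precomputed
#' \code{sigma}. Sensitivities are computed as
#' \eqn{\sigma = 1 - S_{modified}/S_{native}} whenever the richness pair is
#' present; a precomputed \code{sigma} that disagrees with the computed
#' value by more than \code{1e-6} is flagged (the computed value wins).
#'
#' Rows failing validation (unknown vocabulary level, \code{s_native = 0},
#' \code{sigma > 1}, missing values) are excluded, reported with their
#' file line numbers in a warning, and returned in the \code{"rejected"}
#' attribute — never silently dropped.
#'
#' @param path Path to a UTF-8, comma-separated file with a header row.
#' @return Data frame of class \code{sensitivity_db} with columns
#'   \code{study_id}, \code{taxon}, \code{region}, \code{land_use} (all
#'   factors on the closed vocabularies), optional \code{s_native} /
#'   \code{s_modified}, and \code{sigma}. Attribute \code{"rejected"}
#'   holds a data frame of (line, reason) for excluded rows.
#' @export
load_sensitivity_db <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  id_cols <- c("study_id", "taxon", "region", "land_use")
  missing_cols <- setdiff(id_cols, names(raw))
  if (length(missing_cols)) {
    stop(sprintf(
      "missing mandatory column(s): %s",
      paste(missing_cols, collapse = ", ")
    ), call. = FALSE)
  }
  has_pair <- all(c("s_native", "s_modified") %in% names(raw))
  has_sigma <- "sigma" %in% names(raw)
  if (!has_pair && !has_sigma) {
    stop("need either columns `s_native` and `s_modified`, or `sigma`",
      call. = FALSE
    )
  }
  validate_sensitivity_records(raw, has_pair = has_pair, has_sigma = has_sigma)
}

# Shared validation/derivation for file- and code-built record tables.
# Row i of `raw` corresponds to file line i + 1 (header).
validate_sensitivity_records <- function(raw, has_pair, has_sigma) {
  n <- nrow(raw)
  reason <- character(n)
  flag <- function(i, why) {
    reason[i] <<- ifelse(reason[i] == "", why, paste(reason[i], why, sep = "; "))
  }
  bad_vocab <- function(x, levels) is.na(x) | !(x %in% levels)
  for (i in which(bad_vocab(raw$taxon, taxon_levels))) {
    flag(i, sprintf("unknown taxon '%s'", raw$taxon[i]))
  }
  for (i in which(bad_vocab(raw$region, region_levels))) {
    flag(i, sprintf("unknown region '%s'", raw$region[i]))
  }
  for (i in which(bad_vocab(raw$land_use, land_use_levels))) {
    flag(i, sprintf("unknown land_use '%s'", raw$land_use[i]))
  }
  sigma <- rep(NA_real_, n)
  if (has_pair) {
    pair_ok <- !is.na(raw$s_native) & !is.na(raw$s_modified)
    for (i in which(pair_ok & raw$s_native == 0)) {
      flag(i, "undefined sensitivity (s_native = 0)")
    }
    for (i in which(pair_ok & (raw$s_native < 0 | raw$s_modified < 0))) {
      flag(i, "negative richness")
    }
    usable <- pair_ok & raw$s_native > 0 & raw$s_modified >= 0
    sigma[usable] <- 1 - raw$s_modified[usable] / raw$s_native[usable]
  }
  if (has_sigma) {
    direct <- !is.na(raw$sigma)
    for (i in which(direct & raw$sigma > 1)) flag(i, "sigma > 1")
    both <- direct & !is.na(sigma)
    disagree <- which(both & abs(raw$sigma - sigma) > 1e-6)
    if (length(disagree)) {
      warning(sprintf(
        "line(s) %s: reported sigma disagrees with the richness pair; using the computed value",
        paste(disagree + 1L, collapse = ", ")
      ), call. = FALSE)
    }
    take_direct <- direct & is.na(sigma) & raw$sigma <= 1
    sigma[take_direct] <- raw$sigma[take_direct]
  }
  for (i in which(is.na(sigma) & reason == "")) {
    flag(i, "no usable sigma or richness pair")
  }
  bad <- reason != ""
  if (any(bad)) {
    warning(sprintf(
      "%d row(s) excluded: %s", sum(bad),
      paste(sprintf("line %d (%s)", which(bad) + 1L, reason[bad]),
        collapse = "; "
      )
    ), call. = FALSE)
  }
  out <- data.frame(
    study_id = as.character(raw$study_id[!bad]),
    taxon = factor(raw$taxon[!bad], levels = taxon_levels),
    region = factor(raw$region[!bad], levels = region_levels),
    land_use = factor(raw$land_use[!bad], levels = land_use_levels),
    stringsAsFactors = FALSE
  )
  if (has_pair) {
    out$s_native <- raw$s_native[!bad]
    out$s_modified <- raw$s_modified[!bad]
  }
  out$sigma <- sigma[!bad]
  attr(out, "rejected") <- data.frame(
    line = which(bad) + 1L, reason = reason[bad],
    stringsAsFactors = FALSE
  )
  class(out) <- c("sensitivity_db", "data.frame")
  out
}

#' Group summaries of plot-scale sensitivities
#'
#' Per-group record count, mean sensitivity, standard error of the mean
#' (\eqn{sd/\sqrt{n}}; reported as 0 with \code{se_defined = FALSE} for
#' singleton groups), and the sigma range. Empty factor combinations are
#' omitted.
#'
#' @param records A \code{sensitivity_db} (or any data frame with a
#'   \code{sigma} column and the grouping columns).
#' @param keys Character vector of grouping columns, e.g.
#'   \code{c("land_use", "region")}.
#' @return Data frame with the grouping columns plus \code{n},
#'   \code{mean_sigma}, \code{se_sigma}, \code{se_defined},
#'   \code{min_sigma}, \code{max_sigma}.
#' @export
summarize_groups <- function(records, keys = c("land_use", "region")) {
  if (nrow(records) == 0) stop("no records to summarise", call. = FALSE)
  if (!all(keys %in% names(records))) {
    stop("grouping key(s) not present in the records", call. = FALSE)
  }
  parts <- split(records, records[keys], drop = TRUE)
  rows <- lapply(parts, function(d) {
    g <- d[1, keys, drop = FALSE]
    n <- nrow(d)
    cbind(g, data.frame(
      n = n,
      mean_sigma = mean(d$sigma),
      se_sigma = if (n > 1) stats::sd(d$sigma) / sqrt(n) else 0,
      se_defined = n > 1,
      min_sigma = min(d$sigma),
      max_sigma = max(d$sigma),
      stringsAsFactors = FALSE
    ))
  })
  out <- do.call(rbind, rows)
  out <- out[do.call(order, out[keys]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Three-way factorial ANOVA of plot-scale sensitivities
#'
#' Fits the linear model of sigma on taxon, land-use class and region with
#' all two-way interactions, and reports per-effect degrees of freedom,
#' sums of squares, F, p, and the classical effect size
#' \eqn{\eta^2 = SS_{effect} / SS_{total}} (share of the corrected total
#' sum of squares). Type II sums of squares are the default for this
#' unbalanced design; Type I (sequential) is available, and is the
#' decomposition whose effect SS add up exactly to the total.
#' Factors with fewer than two observed levels are dropped with a warning.
#'
#' @param records A \code{sensitivity_db}.
#' @param ss_type 2 (default) or 1.
#' @return Data frame of class \code{anova_table} with columns
#'   \code{effect}, \code{df}, \code{sum_sq}, \code{mean_sq},
#'   \code{f_value}, \code{p_value}, \code{eta_sq}, ending in a Residuals
#'   and a Total row. The fitted \code{lm} is attached as attribute
#'   \code{"fit"}.
#' @export
three_way_anova <- function(records, ss_type = 2) {
  if (!ss_type %in% c(1, 2)) stop("`ss_type` must be 1 or 2", call. = FALSE)
  d <- droplevels(as.data.frame(records))
  factors <- c("taxon", "land_use", "region")
  keep <- factors[vapply(factors, function(f) nlevels(d[[f]]) >= 2, logical(1))]
  dropped <- setdiff(factors, keep)
  if (length(dropped)) {
    warning(sprintf(
      "factor(s) with a single level dropped: %s",
      paste(dropped, collapse = ", ")
    ), call. = FALSE)
  }
  if (!length(keep)) stop("no factor has two or more levels", call. = FALSE)
  rhs <- if (length(keep) == 1) keep else sprintf("(%s)^2", paste(keep, collapse = " + "))
  fit <- stats::lm(stats::reformulate(rhs, response = "sigma"), data = d)
  if (ss_type == 1) {
    at <- stats::anova(fit)
  } else {
    at <- car::Anova(fit, type = 2)
  }
  at <- as.data.frame(at)
  effects <- rownames(at)
  ss <- at[["Sum Sq"]]
  df <- at[["Df"]]
  fv <- at[["F value"]]
  pv <- at[["Pr(>F)"]]
  ss_total <- sum((d$sigma - mean(d$sigma))^2)
  out <- data.frame(
    effect = effects,
    df = df,
    sum_sq = ss,
    mean_sq = ss / df,
    f_value = fv,
    p_value = pv,
    eta_sq = ss / ss_total,
    stringsAsFactors = FALSE
  )
  out <- rbind(out, data.frame(
    effect = "Total", df = nrow(d) - 1, sum_sq = ss_total,
    mean_sq = NA_real_, f_value = NA_real_, p_value = NA_real_,
    eta_sq = 1
  ))
  rownames(out) <- NULL
  attr(out, "ss_type") <- ss_type
  attr(out, "fit") <- fit
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Habitat affinities per group of the sensitivity database
#'
#' Converts each group's mean sensitivity into a countryside-SAR affinity,
#' \eqn{h = (1 - \bar\sigma)^{1/z}}. Groups with a negative mean
#' sensitivity get \eqn{h > 1} (modified habitat richer than native).
#'
#' @inheritParams summarize_groups
#' @param z SAR exponent used in the conversion.
#' @return The [summarize_groups()] table with an extra \code{affinity}
#'   column and the \code{z} used attached as an attribute.
#' @export
affinity_table <- function(records, z = 0.2, keys = c("land_use", "region")) {
  out <- summarize_groups(records, keys)
  out$affinity <- affinity_from_sensitivity(out$mean_sigma, z)
  attr(out, "z") <- z
  out
}
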