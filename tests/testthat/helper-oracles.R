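# Independent oracles used across the suite. None of these call the code
# paths they check.

# Connected components of native cells via the lattice adjacency graph
# (igraph), independent of the package's flood fill.
igraph_fragment_count <- function(cells) {
  side <- nrow(cells)
  native <- which(cells == 1L)
  if (!length(native)) {
    return(0L)
  }
  idx <- stats::setNames(seq_along(native), native)
  edges <- integer(0)
  for (i in native) {
    r <- (i - 1L) %% side + 1L
    cl <- (i - 1L) %/% side + 1L
    for (nb in c(
      if (r < side) i + 1L,
      if (cl < side) i + side
    )) {
      if (cells[nb] == 1L) edges <- c(edges, idx[[as.character(i)]], idx[[as.character(nb)]])
    }
  }
  g <- igraph::make_empty_graph(n = length(native), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::components(g)$no
}

# Brute-force per-window modified fractions by explicit double loop over
# window corners (no rowsum tricks).
brute_window_fractions <- function(cells, omega) {
  side <- nrow(cells)
  out <- c()
  for (cw in seq(1, side, by = omega)) {
    for (rw in seq(1, side, by = omega)) {
      block <- cells[rw:(rw + omega - 1), cw:(cw + omega - 1)]
      out <- c(out, sum(block == 0L) / omega^2)
    }
  }
  out
}

# From-scratch sums of squares for a balanced factorial with two-way
# interactions, using cell/marginal means only (no lm machinery).
balanced_anova_ss <- function(d, factors) {
  y <- d$sigma
  gm <- mean(y)
  n <- nrow(d)
  ss <- list()
  main_eff <- list()
  for (f in factors) {
    means <- tapply(y, d[[f]], mean)
    counts <- tapply(y, d[[f]], length)
    main_eff[[f]] <- means - gm
    ss[[f]] <- sum(counts * (means - gm)^2)
  }
  pairs <- utils::combn(factors, 2, simplify = FALSE)
  for (p in pairs) {
    cm <- tapply(y, list(d[[p[1]]], d[[p[2]]]), mean)
    cn <- tapply(y, list(d[[p[1]]], d[[p[2]]]), length)
    dev <- sweep(sweep(cm - gm, 1, main_eff[[p[1]]]), 2, main_eff[[p[2]]])
    ss[[paste(p, collapse = ":")]] <- sum(cn * dev^2)
  }
  ss$total <- sum((y - gm)^2)
  ss
}

# Tiny balanced factorial dataset with known cell means and optional noise.
make_balanced_db <- function(n_per_cell = 4, noise_sd = 0, seed = 99) {
  set.seed(seed)
  cells <- expand.grid(
    taxon = c("bird", "plant"),
    land_use = c(
      "annual_crops", "managed_forest", "permanent_crops",
      "pastures", "urban"
    ),
    region = c("tropical", "temperate"),
    stringsAsFactors = FALSE
  )
  lu_eff <- c(
    annual_crops = 0.2, managed_forest = -0.2, permanent_crops = 0.3,
    pastures = -0.1, urban = 0
  )
  tx_eff <- c(bird = 0.05, plant = -0.05)
  rg_eff <- c(tropical = 0.1, temperate = -0.1)
  mu <- 0.3 + lu_eff[cells$land_use] + tx_eff[cells$taxon] + rg_eff[cells$region]
  d <- cells[rep(seq_len(nrow(cells)), each = n_per_cell), ]
  d$sigma <- rep(mu, each = n_per_cell) +
    stats::rnorm(nrow(d), 0, noise_sd) +
    # deterministic within-cell jitter so SS_residual > 0 even at noise_sd = 0
    rep(c(-0.01, 0.01), length.out = nrow(d))
  d$study_id <- sprintf("s%03d", seq_len(nrow(d)))
  d$taxon <- factor(d$taxon)
  d$land_use <- factor(d$land_use)
  d$region <- factor(d$region)
  rownames(d) <- NULL
  d
}

# Write a sensitivity CSV and return its path.
write_db_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}
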