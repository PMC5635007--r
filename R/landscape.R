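#' Construct a landscape object from a binary habitat matrix
#'
#' A landscape is a square lattice whose cells are either native habitat
#' (1) or human-modified habitat (0). Fragments are maximal 4-connected
#' (von Neumann) patches of native cells on a bounded lattice (no wrap).
#'
#' @param cells Square integer/logical matrix; 1 (or TRUE) marks native
#'   habitat, 0 modified habitat.
#' @param seed Optional integer recording the RNG seed that produced the
#'   landscape (for provenance only; not used here).
#' @return An object of class \code{sar_landscape}: a list with elements
#'   \code{side}, \code{cells}, \code{native_cells}, \code{native_fraction},
#'   \code{n_fragments} and \code{seed}.
#' @export
as_landscape <- function(cells, seed = NA_integer_) {
  cells <- as.matrix(cells)
  if (nrow(cells) != ncol(cells)) {
    stop("`cells` must be a square matrix", call. = FALSE)
  }
  storage.mode(cells) <- "integer"
  if (!all(cells %in% c(0L, 1L))) {
    stop("`cells` must be binary (0 = modified, 1 = native)", call. = FALSE)
  }
  structure(
    list(
      side = nrow(cells),
      cells = cells,
      native_cells = sum(cells),
      native_fraction = mean(cells),
      n_fragments = count_fragments(cells),
      seed = seed
    ),
    class = "sar_landscape"
  )
}

#' @export
print.sar_landscape <- function(x, ...) {
  cat(sprintf(
    "Landscape: %d x %d cells, %d native (%.1f%%), %d fragment(s)\n",
    x$side, x$side, x$native_cells, 100 * x$native_fraction,
    ifelse(is.na(x$n_fragments), -1L, x$n_fragments)
  ))
  invisible(x)
}

#' Generate a random binary landscape
#'
#' Places exactly \code{round(native_fraction * side^2)} native cells
#' uniformly at random without replacement on a \code{side x side} lattice.
#' At the default study conditions (side 64, 10\% native) this is 410
#' native cells.
#'
#' @param side Cells per lattice edge, \code{>= 2}.
#' @param native_fraction Proportion of cells that are native habitat,
#'   strictly between 0 and 1 (and not rounding to an empty or full
#'   lattice).
#' @param seed Optional integer seed for reproducibility.
#' @param audit_fragments Count native fragments by flood fill (default
#'   \code{TRUE}). Set \code{FALSE} to skip the count in large sweeps where
#'   fragmentation is not of interest; \code{n_fragments} is then \code{NA}.
#' @return A \code{sar_landscape}.
#' @examples
#' L <- generate_random_landscape(64, 0.10, seed = 1)
#' L$native_cells # 410
#' @export
generate_random_landscape <- function(side, native_fraction, seed = NULL,
                                      audit_fragments = TRUE) {
  if (side < 2 || side != round(side)) {
    stop("`side` must be an integer >= 2", call. = FALSE)
  }
  if (native_fraction <= 0 || native_fraction >= 1) {
    stop("`native_fraction` must be in (0, 1)", call. = FALSE)
  }
  n_native <- round(native_fraction * side^2)
  if (n_native < 1 || n_native >= side^2) {
    stop("degenerate landscape: `native_fraction` rounds to an empty or full lattice",
      call. = FALSE
    )
  }
  if (!is.null(seed)) set.seed(seed)
  cells <- matrix(0L, side, side)
  cells[sample.int(side^2, n_native)] <- 1L
  structure(
    list(
      side = side,
      cells = cells,
      native_cells = n_native,
      native_fraction = n_native / side^2,
      n_fragments = if (audit_fragments) count_fragments(cells) else NA_integer_,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
    ),
    class = "sar_landscape"
  )
}

#' Generate a landscape with a controlled number of native fragments
#'
#' Builds a landscape whose native cells form exactly \code{n_fragments}
#' 4-connected patches, spanning the fragmentation gradient from a single
#' compact fragment to fully scattered single-cell fragments (at the
#' default conditions, 1 fragment of 410 cells up to 410 one-cell
#' fragments).
#'
#' The algorithm seeds \code{n_fragments} mutually non-adjacent cells at
#' random, then grows patches by uniformly random accretion of 4-neighbour
#' frontier cells, round-robin across patches, rejecting any cell that
#' would touch another patch, until the native-cell budget is spent. If the
#' packing deadlocks the whole attempt is discarded and retried.
#'
#' @inheritParams generate_random_landscape
#' @param n_fragments Requested number of native fragments, between 1 and
#'   the native cell count.
#' @param max_tries Attempts before giving up on an infeasible packing.
#' @return A \code{sar_landscape}; its \code{n_fragments} field is verified
#'   against an independent flood-fill count of the generated cells.
#' @examples
#' L <- generate_clustered_landscape(8, 0.25, n_fragments = 2, seed = 7)
#' L$n_fragments # 2
#' @export
generate_clustered_landscape <- function(side, native_fraction, n_fragments,
                                         seed = NULL, max_tries = 50) {
  if (side < 2 || side != round(side)) {
    stop("`side` must be an integer >= 2", call. = FALSE)
  }
  if (native_fraction <= 0 || native_fraction >= 1) {
    stop("`native_fraction` must be in (0, 1)", call. = FALSE)
  }
  n_native <- round(native_fraction * side^2)
  if (n_native < 1 || n_native >= side^2) {
    stop("degenerate landscape: `native_fraction` rounds to an empty or full lattice",
      call. = FALSE
    )
  }
  if (n_fragments < 1 || n_fragments > n_native) {
    stop("`n_fragments` must be between 1 and the native cell count",
      call. = FALSE
    )
  }
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(max_tries)) {
    cells <- grow_fragments(side, n_native, n_fragments)
    if (!is.null(cells)) {
      found <- count_fragments(cells)
      if (found != n_fragments) next # merged patches; reject and retry
      return(structure(
        list(
          side = side,
          cells = cells,
          native_cells = n_native,
          native_fraction = n_native / side^2,
          n_fragments = found,
          seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
        ),
        class = "sar_landscape"
      ))
    }
  }
  stop(sprintf(
    "could not pack %d fragments of %d native cells on a %d x %d lattice in %d tries",
    n_fragments, n_native, side, side, max_tries
  ), call. = FALSE)
}

# One packing attempt; NULL on deadlock.
grow_fragments <- function(side, n_native, n_fragments) {
  n2 <- side * side
  lab <- integer(n2)
  # seed fragments at mutually non-adjacent cells
  placed <- 0L
  for (i in sample.int(n2)) {
    nb <- neighbours4(i, side)
    if (lab[i] == 0L && all(lab[nb] == 0L)) {
      placed <- placed + 1L
      lab[i] <- placed
      if (placed == n_fragments) break
    }
  }
  if (placed < n_fragments) {
    return(NULL)
  }
  budget <- n_native - n_fragments
  frontier <- lapply(which(lab > 0L), function(i) neighbours4(i, side))
  frontier <- frontier[order(lab[lab > 0L])]
  active <- rep(TRUE, n_fragments)
  while (budget > 0L) {
    progressed <- FALSE
    for (p in which(active)) {
      if (budget == 0L) break
      repeat {
        f <- frontier[[p]]
        if (!length(f)) {
          active[p] <- FALSE
          break
        }
        j <- if (length(f) == 1L) 1L else sample.int(length(f), 1L)
        cand <- f[j]
        frontier[[p]] <- f[-j]
        if (lab[cand] != 0L) next
        nb <- neighbours4(cand, side)
        nl <- lab[nb]
        if (any(nl != 0L & nl != p)) next # would merge with another patch
        lab[cand] <- p
        frontier[[p]] <- c(frontier[[p]], nb[lab[nb] == 0L])
        budget <- budget - 1L
        progressed <- TRUE
        break
      }
    }
    if (!progressed && budget > 0L) {
      return(NULL)
    }
  }
  matrix(as.integer(lab > 0L), side, side)
}

# 4-neighbourhood of linear index i on a bounded side x side lattice
# (column-major, as R matrices are stored)
neighbours4 <- function(i, side) {
  r <- (i - 1L) %% side + 1L
  cl <- (i - 1L) %/% side + 1L
  nb <- integer(0)
  if (r > 1L) nb <- c(nb, i - 1L)
  if (r < side) nb <- c(nb, i + 1L)
  if (cl > 1L) nb <- c(nb, i - side)
  if (cl < side) nb <- c(nb, i + side)
  nb
}

#' Count native-habitat fragments
#'
#' Flood-fill (depth-first) count of maximal 4-connected patches of native
#' cells. Hard lattice edges; no diagonal adjacency.
#'
#' @param cells Binary habitat matrix (1 = native) or a
#'   \code{sar_landscape}.
#' @return Integer fragment count (0 for a landscape with no native cells).
#' @export
count_fragments <- function(cells) {
  if (inherits(cells, "sar_landscape")) cells <- cells$cells
  side <- nrow(cells)
  lab <- integer(length(cells))
  native <- which(cells == 1L)
  count <- 0L
  stack <- integer(length(native))
  for (s in native) {
    if (lab[s] != 0L) next
    count <- count + 1L
    top <- 1L
    stack[1L] <- s
    lab[s] <- count
    while (top > 0L) {
      cur <- stack[top]
      top <- top - 1L
      for (nb in neighbours4(cur, side)) {
        if (cells[nb] == 1L && lab[nb] == 0L) {
          lab[nb] <- count
          top <- top + 1L
          stack[top] <- nb
        }
      }
    }
  }
  count
}

#' Partition a landscape into non-overlapping square sampling windows
#'
#' Tiles the lattice, aligned to the origin, with windows of edge
#' \code{omega} (which must divide the lattice side) and reports the
#' human-modified area fraction of each window. The number of windows is
#' \eqn{N(\Omega) = (side/\Omega)^2}, and the per-window modified cells sum
#' to the landscape total (conservation).
#'
#' @param landscape A \code{sar_landscape}.
#' @param omega Window edge length in cells; must divide \code{side}.
#' @return An object of class \code{window_grid}: list with \code{omega},
#'   \code{window_cells} (\eqn{\Omega^2}), \code{n_windows} and
#'   \code{modified_fractions} (converted-area fraction per window).
#' @export
partition_windows <- function(landscape, omega) {
  stopifnot(inherits(landscape, "sar_landscape"))
  side <- landscape$side
  if (omega < 1 || omega != round(omega) || side %% omega != 0) {
    stop("`omega` must be a positive integer dividing the lattice side",
      call. = FALSE
    )
  }
  modified <- 1L - landscape$cells
  grp <- rep(seq_len(side %/% omega), each = omega)
  counts <- rowsum(t(rowsum(modified, grp)), grp) # per-window modified cells
  structure(
    list(
      omega = as.integer(omega),
      window_cells = as.integer(omega^2),
      n_windows = as.integer((side %/% omega)^2),
      modified_fractions = as.vector(counts) / omega^2
    ),
    class = "window_grid"
  )
}

#' Doubling sequence of sampling-window sizes
#'
#' For a power-of-two lattice side returns the doubling sequence
#' 1, 2, 4, ..., side; otherwise all divisors of the side, so every size
#' tiles the lattice exactly.
#'
#' @param side Lattice edge length, positive integer.
#' @return Increasing integer vector of window edge lengths.
#' @examples
#' window_sizes(64) # 1 2 4 8 16 32 64
#' @export
window_sizes <- function(side) {
  if (side < 1 || side != round(side)) {
    stop("`side` must be a positive integer", call. = FALSE)
  }
  side <- as.integer(side)
  if (bitwAnd(side, side - 1L) == 0L) {
    as.integer(2^(0:round(log2(side))))
  } else {
    divs <- seq_len(side)
    divs[side %% divs == 0L]
  }
}
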