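#' Generate census-style child population snapshots
#'
#' Lays a regular grid of square cells over the region and, for each snapshot
#' date, draws cell-level child counts from a multinomial whose probabilities
#' come from a mixture of Gaussian population centers. Center intensity shares
#' drift linearly between the first and last snapshot, so the population both
#' grows locally and shifts regionally -- the feature the Monte Carlo null has
#' to absorb.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `population_model`: a list with `dates`
#'   (snapshot dates), `cells` (data frame of cell center coordinates `x`,
#'   `y`), `counts` (matrix, cells x snapshots), `cell_size_m`, `region`, and
#'   the `centers` actually used.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  ext <- config$region_extent
  h <- config$cell_size_m
  cx <- seq(ext[1] + h / 2, ext[2], by = h)
  cy <- seq(ext[3] + h / 2, ext[4], by = h)
  cells <- expand.grid(x = cx, y = cy, KEEP.OUT.ATTRS = FALSE)

  with_seed(config$seed, {
    centers <- config$centers
    if (is.null(centers)) {
      k <- config$n_population_centers
      mx <- 0.05 * diff(ext[1:2])
      my <- 0.05 * diff(ext[3:4])
      w0 <- stats::rgamma(k, shape = 1)
      w1 <- w0 * exp(stats::rnorm(k, sd = 0.5))
      centers <- data.frame(
        x = stats::runif(k, ext[1] + mx, ext[2] - mx),
        y = stats::runif(k, ext[3] + my, ext[4] - my),
        sd_m = stats::runif(k, 2000, 8000),
        weight_start = w0 / sum(w0),
        weight_end = w1 / sum(w1)
      )
    }
    dts <- as.numeric(config$snapshot_dates)
    frac <- if (diff(range(dts)) > 0) (dts - dts[1]) / (dts[length(dts)] - dts[1]) else rep(0, length(dts))
    # per-center squared distances to every cell, computed once
    dens <- vapply(seq_len(nrow(centers)), function(c_i) {
      d2 <- (cells$x - centers$x[c_i])^2 + (cells$y - centers$y[c_i])^2
      stats::dnorm(sqrt(d2), sd = centers$sd_m[c_i])
    }, numeric(nrow(cells)))
    counts <- matrix(0L, nrow(cells), length(dts))
    for (s in seq_along(dts)) {
      w <- (1 - frac[s]) * centers$weight_start + frac[s] * centers$weight_end
      w <- w / sum(w)
      p <- as.vector(dens %*% w)
      p <- p + 1e-9 * max(p)   # floor keeps total intensity positive everywhere
      counts[, s] <- stats::rmultinom(1, config$n_children, p)[, 1]
    }
    structure(
      list(dates = config$snapshot_dates, cells = cells, counts = counts,
           cell_size_m = h, region = ext, centers = centers),
      class = "population_model"
    )
  })
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("Child population model: %d cells (%.0f m), %d snapshots %s..%s\n",
              nrow(x$cells), x$cell_size_m, length(x$dates),
              format(min(x$dates)), format(max(x$dates))))
  cat(sprintf("  children per snapshot: %s\n",
              paste(colSums(x$counts), collapse = ", ")))
  invisible(x)
}

# Interpolation weights of a date vector onto the snapshot axis:
# linear between snapshots, nearest snapshot outside the covered range.
# Returns list(lo, hi, w): intensity(d) = (1-w)*counts[,lo] + w*counts[,hi].
snapshot_weights <- function(population, dates) {
  dts <- as.numeric(population$dates)
  d <- as.numeric(dates)
  lo <- findInterval(d, dts)
  lo <- pmin(pmax(lo, 1L), length(dts))
  hi <- pmin(lo + 1L, length(dts))
  w <- ifelse(hi > lo, (d - dts[lo]) / (dts[hi] - dts[lo]), 0)
  w <- pmin(pmax(w, 0), 1)
  list(lo = lo, hi = hi, w = w)
}

#' Time-interpolated child population intensity
#'
#' Cell-level expected child counts at arbitrary dates: linear interpolation
#' between the two bracketing snapshots, nearest snapshot outside the range.
#'
#' @param population a `population_model`.
#' @param dates `Date` (or numeric days) vector.
#' @return Matrix of intensities, cells x `length(dates)`.
#' @export
intensity_at <- function(population, dates) {
  sw <- snapshot_weights(population, dates)
  out <- population$counts[, sw$lo, drop = FALSE] * rep(1 - sw$w, each = nrow(population$counts)) +
    population$counts[, sw$hi, drop = FALSE] * rep(sw$w, each = nrow(population$counts))
  if (any(colSums(out) <= 0)) {
    stop("total population intensity is zero at some requested date", call. = FALSE)
  }
  out
}

# Draw one grid cell per case from its date-specific intensity; returns cell
# indices. `weights` from snapshot_weights() on the case birth dates.
sample_cells <- function(population, weights, n_draws_per_case = 1L) {
  ncell <- nrow(population$cells)
  n <- length(weights$lo)
  out <- matrix(0L, n, n_draws_per_case)
  for (i in seq_len(n)) {
    p <- (1 - weights$w[i]) * population$counts[, weights$lo[i]] +
      weights$w[i] * population$counts[, weights$hi[i]]
    tot <- sum(p)
    if (tot <= 0) stop("total population intensity is zero at a case's birth date", call. = FALSE)
    out[i, ] <- sample.int(ncell, n_draws_per_case, replace = TRUE, prob = p)
  }
  out
}

# Uniform jitter of points within their grid cell.
jitter_in_cell <- function(population, cell_idx) {
  h <- population$cell_size_m
  n <- length(cell_idx)
  cbind(
    x = population$cells$x[cell_idx] + stats::runif(n, -h / 2, h / 2),
    y = population$cells$y[cell_idx] + stats::runif(n, -h / 2, h / 2)
  )
}

#' Write / read population snapshots as CSV
#'
#' Long format, one row per cell and snapshot, columns
#' `snapshot_date` (ISO-8601), `x`, `y` (cell center, meters), `child_count`.
#' Only occupied or zero cells on the stored grid are kept; the grid spacing
#' is re-inferred on read (or can be given explicitly).
#'
#' @param population a `population_model`.
#' @param path CSV file path.
#' @export
write_population <- function(population, path) {
  long <- do.call(rbind, lapply(seq_along(population$dates), function(s) {
    data.frame(snapshot_date = format(population$dates[s]),
               x = population$cells$x, y = population$cells$y,
               child_count = population$counts[, s])
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @param path CSV file path.
#' @param cell_size_m optional explicit grid spacing; inferred from the cell
#'   coordinates when `NULL`.
#' @export
read_population <- function(path, cell_size_m = NULL) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("snapshot_date", "x", "y", "child_count")
  missing_cols <- setdiff(need, names(long))
  if (length(missing_cols)) {
    stop("population CSV is missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(long$child_count < 0)) stop("negative child counts in population CSV", call. = FALSE)
  dates <- sort(unique(as.Date(long$snapshot_date)))
  if (length(dates) < 2) stop("at least 2 population snapshots are required", call. = FALSE)
  key <- paste(long$x, long$y)
  cells_u <- long[!duplicated(key), c("x", "y")]
  rownames(cells_u) <- NULL
  counts <- matrix(0L, nrow(cells_u), length(dates))
  cell_of <- match(key, paste(cells_u$x, cells_u$y))
  snap_of <- match(as.Date(long$snapshot_date), dates)
  counts[cbind(cell_of, snap_of)] <- as.integer(long$child_count)
  if (is.null(cell_size_m)) {
    ux <- sort(unique(cells_u$x)); uy <- sort(unique(cells_u$y))
    gaps <- c(diff(ux), diff(uy))
    cell_size_m <- if (length(gaps)) min(gaps) else 1000
  }
  structure(
    list(dates = dates, cells = cells_u, counts = counts,
         cell_size_m = cell_size_m,
         region = c(min(cells_u$x) - cell_size_m / 2, max(cells_u$x) + cell_size_m / 2,
                    min(cells_u$y) - cell_size_m / 2, max(cells_u$y) + cell_size_m / 2),
         centers = NULL),
    class = "population_model"
  )
}
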