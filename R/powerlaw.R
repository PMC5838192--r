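#' Fit a power law y = a * x^b by log-log least squares
#'
#' The NetworkAnalyzer-style fit used to assess scale-free structure: a
#' least-squares line through `(ln x, ln y)` gives the exponent `b` (slope)
#' and coefficient `a` (exp of the intercept). Two goodness statistics are
#' reported, following the convention that makes them distinct: `correlation`
#' is the Pearson correlation of the *untransformed* points and `r_squared`
#' is the coefficient of determination of the log-log line. Points with
#' nonpositive x or y are dropped before fitting (logged via a message).
#'
#' @param x,y numeric vectors of equal length; alternatively `x` may be a
#'   two-column data frame or matrix of (x, y) points.
#' @return an object of class `power_law_fit`: list with `a`, `b`,
#'   `correlation`, `r_squared`, `n_points` (points used), `n_dropped`
#'   (nonpositive points removed).
#' @examples
#' x <- 1:50
#' fit_power_law(x, 30.370 * x^-0.866)
#' @export
fit_power_law <- function(x, y = NULL) {
  if (is.null(y)) {
    pts <- as.data.frame(x)
    stopifnot(ncol(pts) >= 2L)
    y <- as.numeric(pts[[2L]]); x <- as.numeric(pts[[1L]])
  }
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  n_dropped <- sum(!ok)
  if (n_dropped > 0L)
    message(sprintf("fit_power_law: dropped %d nonpositive/non-finite point(s)", n_dropped))
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) stop("fewer than 2 usable points for a power-law fit")
  if (length(unique(x)) < 2L) stop("all x values equal; power-law fit undefined")
  lx <- log(x); ly <- log(y)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  b <- unname(fit$coefficients[2L])
  a <- exp(unname(fit$coefficients[1L]))
  rss <- sum(fit$residuals^2)
  tss <- sum((ly - mean(ly))^2)
  r2 <- if (tss > 0) max(0, min(1, 1 - rss / tss)) else as.numeric(rss <= 1e-24)
  corr <- if (stats::sd(y) > 0) stats::cor(x, y) else NA_real_
  structure(list(a = a, b = b, correlation = corr, r_squared = r2,
                 n_points = length(x), n_dropped = n_dropped),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> y = %.4g * x^%.4g  (correlation %.3f, R-squared %.3f, %d points)\n",
              x$a, x$b, ifelse(is.na(x$correlation), NaN, x$correlation),
              x$r_squared, x$n_points))
  invisible(x)
}

#' Degree histogram of a centrality table
#'
#' @param table a [centrality_table()]
#' @return a data frame with columns `k` (strictly increasing observed
#'   degree) and `count` (nodes of that degree); counts sum to the number
#'   of nodes.
#' @export
degree_histogram <- function(table) {
  if (!nrow(table)) stop("empty centrality table")
  tab <- table(table$degree)
  data.frame(k = as.integer(names(tab)), count = as.integer(tab))
}

# equal-width binning of a continuous metric: (bin midpoint, count) pairs,
# empty bins omitted
.bin_metric <- function(values, bins = 20L) {
  rng <- range(values)
  if (diff(rng) == 0) return(data.frame(x = rng[1L], y = length(values)))
  breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  keep <- h$counts > 0L
  data.frame(x = h$mids[keep], y = h$counts[keep])
}

#' Scale-free assessment of a component's centrality distributions
#'
#' Fits power laws to three distributions of one connected component: the
#' degree histogram (x = degree, y = node count) and the binned
#' distributions of betweenness and closeness (nodes grouped into
#' equal-width bins over the metric range; x = bin midpoint, y = bin
#' count). Zero metric values (e.g. the betweenness of leaf nodes) are
#' excluded before binning, with the exclusion count recorded. A metric
#' whose distribution cannot be fitted (e.g. constant values) is reported
#' as not assessable, with the reason.
#'
#' @param table a [centrality_table()]
#' @param bins number of equal-width bins for the continuous metrics
#' @return an object of class `scale_free_report`: a named list of entries
#'   for `degree`, `betweenness`, `closeness`, each either a
#'   [fit_power_law()] result (plus `metric` and `n_dropped`) or a record
#'   with `metric` and `error`.
#' @export
scale_free_report <- function(table, bins = 20L) {
  fits <- list()
  fit_one <- function(metric, x, y, n_zero) {
    res <- tryCatch(suppressMessages(fit_power_law(x, y)),
                    error = function(e) list(metric = metric, error = conditionMessage(e)))
    if (inherits(res, "power_law_fit")) {
      res$metric <- metric
      res$n_dropped <- res$n_dropped + n_zero
      if (n_zero > 0L)
        message(sprintf("scale_free_report: %d zero %s value(s) excluded from log-log fit",
                        n_zero, metric))
    }
    res
  }
  hist <- degree_histogram(table)
  fits$degree <- fit_one("degree", hist$k, hist$count, sum(table$degree == 0L))
  for (metric in c("betweenness", "closeness")) {
    v <- table[[metric]]
    n_zero <- sum(v == 0)
    v <- v[v > 0]
    if (length(v) < 2L) {
      fits[[metric]] <- list(metric = metric, error = "fewer than 2 positive values")
    } else {
      pts <- .bin_metric(v, bins)
      fits[[metric]] <- fit_one(metric, pts$x, pts$y, n_zero)
    }
  }
  structure(fits, class = "scale_free_report")
}

#' @export
print.scale_free_report <- function(x, ...) {
  cat("<scale_free_report>\n")
  for (f in x) {
    if (inherits(f, "power_law_fit")) {
      cat(sprintf("  %-12s y = %.4g * x^%.4g  (corr %.3f, R2 %.3f, %d pts, %d dropped)\n",
                  f$metric, f$a, f$b,
                  ifelse(is.na(f$correlation), NaN, f$correlation),
                  f$r_squared, f$n_points, f$n_dropped))
    } else {
      cat(sprintf("  %-12s not scale-free-assessable: %s\n", f$metric, f$error))
    }
  }
  invisible(x)
}

#' Write a scale-free report as JSON
#'
#' One record per metric: `{metric, a, b, correlation, r_squared, n_points,
#' n_dropped}`, or `{metric, error}` when not assessable.
#'
#' @param report a [scale_free_report()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_power_law_report <- function(report, path) {
  recs <- lapply(unclass(report), function(f) {
    if (inherits(f, "power_law_fit"))
      list(metric = f$metric, a = f$a, b = f$b, correlation = f$correlation,
           r_squared = f$r_squared, n_points = f$n_points,
           n_dropped = f$n_dropped)
    else f
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
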