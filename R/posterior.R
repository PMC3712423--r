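#' Propagate covariance draws through a path model
#'
#' Each posterior covariance draw is rescaled to a correlation matrix,
#' repaired to positive definiteness if numerically indefinite (eigenvalue
#' clipping at 1e-8 followed by re-normalization to unit diagonal), and fitted
#' exactly with [fit_paths()]; compound-path values are computed per draw as
#' within-draw products — never as products of summaries. One coefficient
#' vector per directed edge label and per compound label results, carrying the
#' full covariance uncertainty into every path coefficient.
#'
#' Draws whose minimum eigenvalue is below -1e-4 before repair are rejected
#' and logged; more than 5% rejections aborts with an error.
#'
#' @param draws a `covariance_draws` from [fit_mvn_missing()], or a p x p x K
#'   array / list of covariance or correlation matrices with dimnames.
#' @param diagram a [path_diagram()]; its variables must all be present in the
#'   draws.
#' @param compounds optional named list mapping compound labels to ordered
#'   vectors of edge labels (e.g. `list(A = c("10", "13"))`).
#' @return list of class `path_draws`: `draws` (K x labels matrix of
#'   coefficients), `diagram`, `compounds`, `n` (pairwise counts if
#'   available), `n_rejected`, `rejected_log`.
#' @export
propagate <- function(draws, diagram, compounds = NULL) {
  stopifnot(inherits(diagram, "path_diagram"))
  npair <- NULL
  if (inherits(draws, "covariance_draws")) {
    npair <- draws$n
    mats <- draws$draws
  } else if (is.array(draws) && length(dim(draws)) == 3) {
    mats <- draws
  } else if (is.list(draws)) {
    mats <- simplify2array(draws)
  } else stop("unsupported draws input")
  vars <- diagram$variables
  if (is.null(dimnames(mats)[[1]]))
    dimnames(mats)[1:2] <- list(vars, vars)
  if (!all(vars %in% dimnames(mats)[[1]]))
    stop("draws are missing diagram variables: ",
         paste(setdiff(vars, dimnames(mats)[[1]]), collapse = ", "))
  K <- dim(mats)[3]

  labels <- diagram$edges$label
  if (!is.null(compounds)) {
    if (is.null(names(compounds)) || any(!nzchar(names(compounds))))
      stop("compounds must be a named list")
    edf <- diagram$edges
    for (lab in names(compounds)) {
      comp <- as.character(compounds[[lab]])
      miss <- setdiff(comp, edf$label)
      if (length(miss) > 0)
        stop("compound '", lab, "' uses unknown edge labels: ",
             paste(miss, collapse = ", "))
      check_chain(edf, comp)
    }
    labels <- c(labels, names(compounds))
  }

  out <- matrix(NA_real_, K, length(labels), dimnames = list(NULL, labels))
  rejected <- integer(0)
  for (k in seq_len(K)) {
    S <- mats[vars, vars, k]
    d <- diag(S)
    if (any(d <= 0)) { rejected <- c(rejected, k); next }
    R <- stats::cov2cor(S)
    min_ev <- min(eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values)
    if (min_ev < -1e-4) { rejected <- c(rejected, k); next }
    if (min_ev < 1e-8) R <- repair_correlation(R)
    fit <- fit_paths(R, diagram)
    out[k, diagram$edges$label] <- fit$coefficients
    if (!is.null(compounds))
      for (lab in names(compounds))
        out[k, lab] <- prod(fit$coefficients[as.character(compounds[[lab]])])
  }
  if (length(rejected) > K * 0.05)
    stop(length(rejected), " of ", K,
         " draws rejected as indefinite (limit 5%)")
  if (length(rejected) > 0) out <- out[-rejected, , drop = FALSE]
  structure(list(draws = out, diagram = diagram, compounds = compounds,
                 n = npair, n_rejected = length(rejected),
                 rejected_log = rejected),
            class = "path_draws")
}

#' Summarize a vector of per-draw coefficients
#'
#' Point estimate is the Gaussian-KDE mode of the draws (the most likely
#' coefficient value); the 95% credible interval is the 2.5%/97.5% empirical
#' quantiles. The tail probability `p = 2 * min(fraction > 0, fraction < 0)`
#' — how often the estimate falls on the minority side of zero, doubled to be
#' comparable with a two-sided p-value — is floored at 1/(number of draws);
#' the one-sided minority fraction is reported alongside. Support is
#' classified with [classify_support()].
#'
#' @param values numeric vector of at least 100 draws.
#' @param n_pair pairwise sample size to attach (NA when unknown, e.g. for
#'   compound paths).
#' @return One-row data.frame: `point`, `mean`, `lower95`, `upper95`, `p`,
#'   `p_onesided`, `support`, `n`.
#' @export
summarize_draws <- function(values, n_pair = NA_integer_) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("empty draw vector")
  if (length(values) < 100)
    stop("need at least 100 draws to summarize (got ", length(values), ")")
  K <- length(values)
  ci <- unname(stats::quantile(values, c(0.025, 0.975)))
  fp <- mean(values > 0)
  fn <- mean(values < 0)
  p <- min(1, max(2 * min(fp, fn), 1 / K))
  p1 <- max(min(fp, fn), 1 / K)
  data.frame(point = kde_mode(values), mean = mean(values),
             lower95 = ci[1], upper95 = ci[2],
             p = p, p_onesided = p1,
             support = classify_support(ci[1], ci[2], p),
             n = n_pair, stringsAsFactors = FALSE)
}

#' Support classification for a path coefficient
#'
#' `"strong"` when the 95% credible interval does not overlap zero; `"some"`
#' when the interval overlaps zero but the tail probability is below 0.05
#' (an interval only slightly overlapping zero); `"none"` otherwise. This is
#' the bold/italic convention of the study's coefficient tables and the
#' solid/dashed convention of its supported-path diagrams.
#'
#' @param lower95,upper95 credible-interval bounds (vectorized).
#' @param p two-sided tail probability.
#' @return character vector in `{"strong", "some", "none"}`.
#' @export
classify_support <- function(lower95, upper95, p) {
  overlaps <- lower95 <= 0 & upper95 >= 0
  ifelse(!overlaps, "strong", ifelse(p < 0.05, "some", "none"))
}

#' Results table and annotated graph for a propagated path model
#'
#' Assembles the per-edge and per-compound summaries into a coefficient table
#' (path label, hypothesized link, pairwise n, point estimate, mean, 95% CI,
#' tail probabilities, support class) and optionally writes it as CSV together
#' with a DOT rendering that draws only supported edges (solid = strong,
#' dashed = some).
#'
#' @param pd a `path_draws` from [propagate()].
#' @param csv,dot optional output file paths.
#' @return data.frame with one row per directed edge and per compound, with
#'   attribute `"dot"` holding the DOT source.
#' @export
path_report <- function(pd, csv = NULL, dot = NULL) {
  stopifnot(inherits(pd, "path_draws"))
  d <- pd$diagram
  rows <- list()
  for (i in seq_len(nrow(d$edges))) {
    e <- d$edges[i, ]
    n <- if (!is.null(pd$n)) pd$n[e$source, e$target] else NA_integer_
    s <- summarize_draws(pd$draws[, e$label], n_pair = n)
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(label = e$label,
                       link = paste(e$source, "->", e$target),
                       type = "path", stringsAsFactors = FALSE), s)
  }
  for (lab in names(pd$compounds)) {
    comp <- pd$compounds[[lab]]
    s <- summarize_draws(pd$draws[, lab])
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(label = lab,
                       link = paste(comp, collapse = " x "),
                       type = "compound", stringsAsFactors = FALSE), s)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  dot_src <- diagram_to_dot(d, summaries = out[out$type == "path", ])
  attr(out, "dot") <- dot_src
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE, na = "NA")
  if (!is.null(dot)) writeLines(dot_src, dot)
  out
}
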