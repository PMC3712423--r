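#' Fit standardized path coefficients to a correlation matrix
#'
#' For a recursive (acyclic) path model the standardized coefficients have an
#' exact solution: for each endogenous variable y with parent set P,
#' `beta = R[P,P]^-1 R[P,y]` — the partial regression of y on its parents,
#' controlling for all of them simultaneously — with residual variance
#' `psi_y = 1 - R[y,P] beta`. No iterative SEM optimization is needed.
#' Correlation edges between exogenous variables take their matrix entries.
#'
#' @param R symmetric positive-definite correlation matrix (unit diagonal)
#'   whose dimnames match the diagram's variables, or an unnamed matrix in
#'   diagram variable order.
#' @param diagram a [path_diagram()].
#' @return An object of class `path_fit`: `coefficients` (named by edge
#'   label), `edges`, `exog_corr` (named "a~b"), `psi` and `r_squared` (named
#'   by endogenous variable), and the `diagram`.
#' @export
#' @examples
#' d <- parse_diagram(c("1: x -> y", "2: y -> z"))
#' R <- matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3,
#'             dimnames = list(c("x","y","z"), c("x","y","z")))
#' fit_paths(R, d)$coefficients
fit_paths <- function(R, diagram) {
  stopifnot(inherits(diagram, "path_diagram"))
  vars <- diagram$variables
  R <- as.matrix(R)
  if (is.null(dimnames(R))) {
    if (nrow(R) != length(vars)) stop("matrix dimension does not match diagram variables")
    dimnames(R) <- list(vars, vars)
  }
  if (!all(vars %in% rownames(R)))
    stop("matrix is missing diagram variables: ",
         paste(setdiff(vars, rownames(R)), collapse = ", "))
  R <- R[vars, vars]
  if (max(abs(R - t(R))) > 1e-8) stop("matrix is not symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8) stop("matrix does not have unit diagonal")

  coefs <- stats::setNames(numeric(nrow(diagram$edges)), diagram$edges$label)
  psi <- r2 <- stats::setNames(numeric(length(diagram$endogenous)), diagram$endogenous)
  for (v in diagram$endogenous) {
    sel <- diagram$edges$target == v
    P <- diagram$edges$source[sel]
    beta <- tryCatch(solve(R[P, P, drop = FALSE], R[P, v]),
                     error = function(e) stop("singular parent block for '", v, "'"))
    coefs[diagram$edges$label[sel]] <- beta
    r2[v] <- sum(R[v, P] * beta)
    psi[v] <- 1 - r2[v]
  }
  exog_corr <- numeric(0)
  if (nrow(diagram$correlations) > 0) {
    exog_corr <- stats::setNames(
      R[cbind(diagram$correlations$a, diagram$correlations$b)],
      paste(diagram$correlations$a, diagram$correlations$b, sep = "~"))
  }
  structure(list(coefficients = coefs, edges = diagram$edges,
                 exog_corr = exog_corr, psi = psi, r_squared = r2,
                 diagram = diagram),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat("Recursive path model fit:", length(x$coefficients), "paths\n")
  print(round(x$coefficients, 3))
  invisible(x)
}

#' Model-implied correlation matrix of a fitted recursive path model
#'
#' With B the coefficient matrix (entry \[child, parent\] = beta) and Psi the
#' block matrix holding the exogenous correlation block and the endogenous
#' residual variances, the implied covariance of the standardized variables is
#' `(I - B)^-1 Psi (I - B)^-T`. For a valid fit this has unit diagonal, i.e.
#' it is the correlation matrix the model reproduces; entry (i, j) equals the
#' tracing-rule sum over all admissible paths connecting i and j.
#'
#' @param diagram a [path_diagram()] (defaults to the one stored in `fit`).
#' @param fit a `path_fit`, or any list with `coefficients` named by edge
#'   label, `psi` named by endogenous variable and optionally `exog_corr`.
#' @return Correlation matrix in diagram variable order.
#' @export
implied_matrix <- function(diagram, fit) {
  if (missing(diagram)) diagram <- fit$diagram
  stopifnot(inherits(diagram, "path_diagram"))
  vars <- diagram$variables
  p <- length(vars)
  B <- matrix(0, p, p, dimnames = list(vars, vars))
  if (nrow(diagram$edges) > 0)
    B[cbind(diagram$edges$target, diagram$edges$source)] <-
      fit$coefficients[diagram$edges$label]
  Psi <- diag(p); dimnames(Psi) <- list(vars, vars)
  for (v in diagram$endogenous) {
    if (!v %in% names(fit$psi)) stop("missing residual variance for '", v, "'")
    if (fit$psi[v] < -1e-10) stop("negative residual variance for '", v, "'")
    Psi[v, v] <- fit$psi[v]
  }
  if (nrow(diagram$correlations) > 0) {
    key <- paste(diagram$correlations$a, diagram$correlations$b, sep = "~")
    Psi[cbind(diagram$correlations$a, diagram$correlations$b)] <- fit$exog_corr[key]
    Psi[cbind(diagram$correlations$b, diagram$correlations$a)] <- fit$exog_corr[key]
  }
  IB <- diag(p) - B
  M <- tryCatch(solve(IB), error = function(e)
    stop("(I - B) is singular; the diagram/fit is corrupt"))
  out <- M %*% Psi %*% t(M)
  out <- (out + t(out)) / 2
  dimnames(out) <- list(vars, vars)
  out
}

#' Compound-path coefficient: product along a chain of paths
#'
#' The coefficient of a compound (indirect) path is the product of the
#' standardized coefficients of its component paths. Component edges must form
#' an admissible tracing-rule chain: consecutive edges share a variable, and
#' edges may be traversed against their arrow only in an initial backward
#' segment (once the chain runs with the arrows it may not reverse). This
#' admits chains such as exploration <- aggression -> feeding rate as well as
#' plain head-to-tail sequences.
#'
#' @param fit a `path_fit`.
#' @param edge_labels character vector of edge labels, in chain order.
#' @return The product of the named coefficients.
#' @export
compound_coefficient <- function(fit, edge_labels) {
  edge_labels <- as.character(edge_labels)
  miss <- setdiff(edge_labels, names(fit$coefficients))
  if (length(miss) > 0) stop("unknown edge labels: ", paste(miss, collapse = ", "))
  check_chain(fit$edges, edge_labels)
  prod(fit$coefficients[edge_labels])
}

# Validates the tracing-rule chain; errors when consecutive edges do not
# connect or a forward edge is followed by a reversed one.
check_chain <- function(edges, edge_labels) {
  if (length(edge_labels) < 2) return(invisible(TRUE))
  e <- edges[match(edge_labels, edges$label), , drop = FALSE]
  # direction of edge i: +1 traversed source->target, -1 reversed
  n <- nrow(e)
  # resolve the traversal orientation greedily from the first junction
  dir <- integer(n)
  for (i in seq_len(n - 1L)) {
    joins <- c(e$target[i] == e$source[i + 1L],  # fwd-fwd
               e$target[i] == e$target[i + 1L],  # fwd-rev
               e$source[i] == e$source[i + 1L],  # rev-fwd
               e$source[i] == e$target[i + 1L])  # rev-rev
    if (!any(joins))
      stop("broken compound chain between paths '", e$label[i], "' and '",
           e$label[i + 1L], "'")
    if (i == 1L) dir[1L] <- if (joins[1L] || joins[2L]) 1L else -1L
    prev_head <- if (dir[i] == 1L) e$target[i] else e$source[i]
    if (prev_head == e$source[i + 1L]) dir[i + 1L] <- 1L
    else if (prev_head == e$target[i + 1L]) dir[i + 1L] <- -1L
    else stop("broken compound chain between paths '", e$label[i], "' and '",
              e$label[i + 1L], "'")
  }
  # backward segment must precede the forward segment (no fwd -> rev switch)
  if (any(diff(dir) < 0))
    stop("inadmissible compound chain: reversed edge after a forward edge")
  invisible(TRUE)
}
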