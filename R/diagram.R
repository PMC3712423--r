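#' Construct a path diagram
#'
#' A path diagram is a directed acyclic graph of hypothesized causal links
#' between observed variables, plus optional double-headed correlation edges
#' between exogenous variables (variables with no incoming directed edge).
#' Standardized path coefficients are attached to the directed edges by
#' [fit_paths()].
#'
#' @param edges data.frame with columns `source`, `target` and optionally
#'   `label` (unique edge labels, e.g. path numbers; auto-numbered when
#'   absent).
#' @param correlations optional data.frame with columns `a`, `b` naming
#'   unordered pairs of exogenous variables connected by a correlation edge.
#' @param variables optional character vector fixing the variable order;
#'   defaults to first-appearance order in `edges`/`correlations`.
#'
#' @return An object of class `path_diagram` with elements `variables`,
#'   `edges` (source, target, label), `correlations`, `exogenous` and
#'   `endogenous`.
#' @seealso [parse_diagram()] for the plain-text DSL, [fit_paths()].
#' @export
path_diagram <- function(edges, correlations = NULL, variables = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("source", "target") %in% names(edges)))
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if (is.null(edges$label)) edges$label <- as.character(seq_len(nrow(edges)))
  edges$label <- as.character(edges$label)
  if (anyDuplicated(edges$label))
    stop("duplicate edge labels: ", paste(unique(edges$label[duplicated(edges$label)]), collapse = ", "))
  if (any(edges$source == edges$target))
    stop("self-edges are not allowed")
  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate directed edge: ", sub("\r", " -> ", key[duplicated(key)][1]))

  if (!is.null(correlations) && nrow(as.data.frame(correlations)) > 0) {
    correlations <- as.data.frame(correlations, stringsAsFactors = FALSE)
    stopifnot(all(c("a", "b") %in% names(correlations)))
    correlations$a <- as.character(correlations$a)
    correlations$b <- as.character(correlations$b)
    if (any(correlations$a == correlations$b))
      stop("correlation edge must join two distinct variables")
    ckey <- apply(correlations[, c("a", "b")], 1L, function(p) paste(sort(p), collapse = "\r"))
    if (anyDuplicated(ckey)) stop("duplicate correlation edge")
  } else {
    correlations <- data.frame(a = character(), b = character(), stringsAsFactors = FALSE)
  }

  seen <- unique(c(rbind(edges$source, edges$target),
                   rbind(correlations$a, correlations$b)))
  if (is.null(variables)) variables <- seen
  if (!all(seen %in% variables))
    stop("variables missing from `variables`: ", paste(setdiff(seen, variables), collapse = ", "))

  ord <- topological_order(variables, edges)   # errors on cycles
  endo <- unique(edges$target)
  exo <- setdiff(variables, endo)
  bad <- setdiff(unique(c(correlations$a, correlations$b)), exo)
  if (length(bad) > 0)
    stop("correlation edges may only join exogenous variables; endogenous: ",
         paste(bad, collapse = ", "))

  structure(
    list(variables = variables, edges = edges, correlations = correlations,
         exogenous = exo, endogenous = intersect(ord, endo), order = ord),
    class = "path_diagram")
}

# Kahn's algorithm; errors with the offending cycle.
topological_order <- function(variables, edges) {
  indeg <- stats::setNames(integer(length(variables)), variables)
  tab <- table(factor(edges$target, levels = variables))
  indeg[names(tab)] <- as.integer(tab)
  remaining <- edges
  out <- character(0)
  queue <- variables[indeg == 0L]
  while (length(queue) > 0) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    leaving <- remaining$source == v
    for (w in remaining$target[leaving]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
    remaining <- remaining[!leaving, , drop = FALSE]
  }
  if (length(out) < length(variables)) {
    cyc <- setdiff(variables, out)
    stop("directed edges contain a cycle involving: ", paste(cyc, collapse = ", "))
  }
  out
}

#' Parse a path diagram from its plain-text specification
#'
#' Each non-comment line declares one edge:
#' \preformatted{
#'   10: own_feed -> partner_feed    # directed, labelled "10"
#'   A <-> B                         # correlation edge between exogenous A, B
#' }
#' Labels are optional (unlabelled directed edges are numbered in order);
#' `#` starts a comment. Variables are collected in first-appearance order.
#'
#' @param text character: either lines of the DSL or the path of a file to read.
#' @return A [path_diagram()].
#' @export
#' @examples
#' d <- parse_diagram(c("1: aggression -> exploration",
#'                      "2: aggression -> feed_own"))
#' d$exogenous
parse_diagram <- function(text) {
  if (length(text) == 1 && !grepl("[\n>]", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  edges <- list(); corrs <- list()
  for (ln in lines) {
    if (grepl("<->", ln, fixed = TRUE)) {
      parts <- trimws(strsplit(ln, "<->", fixed = TRUE)[[1]])
      if (length(parts) != 2 || !all(nzchar(parts)))
        stop("cannot parse correlation edge: ", ln)
      corrs[[length(corrs) + 1L]] <- data.frame(a = parts[1], b = parts[2])
    } else if (grepl("->", ln, fixed = TRUE)) {
      label <- NA_character_
      if (grepl(":", ln, fixed = TRUE)) {
        label <- trimws(sub(":.*$", "", ln))
        ln <- trimws(sub("^[^:]*:", "", ln))
      }
      parts <- trimws(strsplit(ln, "->", fixed = TRUE)[[1]])
      if (length(parts) != 2 || !all(nzchar(parts)))
        stop("cannot parse directed edge: ", ln)
      edges[[length(edges) + 1L]] <-
        data.frame(source = parts[1], target = parts[2], label = label)
    } else stop("cannot parse line: ", ln)
  }
  if (length(edges) == 0) stop("diagram has no directed edges")
  edges <- do.call(rbind, edges)
  auto <- is.na(edges$label)
  edges$label[auto] <- as.character(seq_len(nrow(edges)))[auto]
  corrs <- if (length(corrs) > 0) do.call(rbind, corrs) else NULL
  path_diagram(edges, corrs)
}

#' @export
print.path_diagram <- function(x, ...) {
  cat("Path diagram:", length(x$variables), "variables,",
      nrow(x$edges), "directed edges,",
      nrow(x$correlations), "correlation edges\n")
  cat("  exogenous: ", paste(x$exogenous, collapse = ", "), "\n", sep = "")
  cat("  endogenous:", paste(x$endogenous, collapse = ", "), "\n")
  invisible(x)
}

#' Export a path diagram to Graphviz DOT format
#'
#' When edge summaries are supplied, only supported edges are drawn — solid
#' for strong support (95% credible interval excluding zero), dashed for some
#' support (interval overlapping zero but tail probability p < 0.05) — the
#' convention used for rendering supported pathways of a fitted model.
#'
#' @param diagram a [path_diagram()].
#' @param summaries optional data.frame from [summarize_draws()] /
#'   [path_report()] with columns `label` and `support`; compound rows are
#'   ignored.
#' @param file optional path; when given the DOT source is also written there.
#' @return The DOT source as a character scalar, invisibly when `file` is set.
#' @export
diagram_to_dot <- function(diagram, summaries = NULL, file = NULL) {
  stopifnot(inherits(diagram, "path_diagram"))
  q <- function(x) paste0('"', x, '"')
  lines <- c("digraph paths {", "  rankdir=LR;", "  node [shape=box];")
  lines <- c(lines, paste0("  ", q(diagram$variables), ";"))
  for (i in seq_len(nrow(diagram$edges))) {
    e <- diagram$edges[i, ]
    style <- "solid"
    extra <- ""
    if (!is.null(summaries)) {
      row <- summaries[summaries$label == e$label, , drop = FALSE]
      if (nrow(row) == 1) {
        if (row$support == "none") next
        style <- if (row$support == "strong") "solid" else "dashed"
        extra <- sprintf(", label=\"%s: %.2f\"", e$label, row$point)
      }
    }
    lines <- c(lines, sprintf("  %s -> %s [style=%s%s];",
                              q(e$source), q(e$target), style, extra))
  }
  for (i in seq_len(nrow(diagram$correlations))) {
    ce <- diagram$correlations[i, ]
    lines <- c(lines, sprintf("  %s -> %s [dir=both, style=solid];",
                              q(ce$a), q(ce$b)))
  }
  lines <- c(lines, "}")
  dot <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(dot, file)
    return(invisible(dot))
  }
  dot
}
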