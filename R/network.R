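# Spearman correlation matrix, thresholded network, and exports.

#' Spearman correlation matrix with pairwise p-values
#'
#' Rank correlations (average ranks for ties) between perfusion parameters
#' and clinical covariates, using pairwise-complete observations. Binary
#' covariates enter as 0/1 (Spearman against a binary variable is the rank
#' biserial; nothing is special-cased). A constant variable yields `NA`
#' correlations for its pairs - flagged, not thrown.
#'
#' @param points Data frame of assessment points.
#' @param variables Columns to correlate (default: all numeric columns).
#' @return List of class `icg_spearman` with matrices `rho`, `p`, `n`
#'   (pairwise complete sample sizes) and the variable names.
#' @export
spearman_matrix <- function(points, variables = NULL) {
  if (is.null(variables))
    variables <- names(points)[vapply(points, is.numeric, logical(1))]
  missing_vars <- setdiff(variables, names(points))
  if (length(missing_vars))
    stop("variables not found: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  x <- as.matrix(points[variables])
  k <- length(variables)
  rho <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  pm <- rho
  nm <- matrix(NA_integer_, k, k, dimnames = list(variables, variables))
  for (i in seq_len(k)) {
    for (j in i:k) {
      ok <- is.finite(x[, i]) & is.finite(x[, j])
      nm[i, j] <- nm[j, i] <- sum(ok)
      if (sum(ok) < 3L) next
      xi <- x[ok, i]; xj <- x[ok, j]
      if (i == j) { rho[i, j] <- 1; pm[i, j] <- NA_real_; next }
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next # constant: NA flagged
      ct <- suppressWarnings(stats::cor.test(xi, xj, method = "spearman",
                                             exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      pm[i, j] <- pm[j, i] <- ct$p.value
    }
  }
  structure(list(rho = rho, p = pm, n = nm, variables = variables),
            class = "icg_spearman")
}

#' @export
print.icg_spearman <- function(x, ...) {
  cat(sprintf("<icg_spearman> %d variables\n", length(x$variables)))
  print(round(x$rho, 2))
  invisible(x)
}

#' Build a thresholded correlation network
#'
#' Edges connect variable pairs whose Spearman rho is strictly above
#' `threshold` (positive class, drawn blue) or strictly below
#' `-threshold` (negative class, drawn red). Self-edges are never
#' included; `NA` correlations produce no edge.
#'
#' @param x An [spearman_matrix()] result, or a symmetric correlation
#'   matrix with unit diagonal.
#' @param threshold Absolute-rho threshold (default 0.2, strict
#'   inequality).
#' @return Object of class `icg_network`: list with `edges` (data frame
#'   `a,b,rho,sign`), `variables`, `threshold` and the `rho` matrix.
#' @export
build_network <- function(x, threshold = 0.2) {
  rho <- if (inherits(x, "icg_spearman")) x$rho else as.matrix(x)
  if (nrow(rho) != ncol(rho)) stop("correlation matrix must be square", call. = FALSE)
  vars <- rownames(rho)
  if (is.null(vars)) vars <- paste0("v", seq_len(nrow(rho)))
  edges <- list()
  k <- nrow(rho)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      r <- rho[i, j]
      if (is.na(r) || abs(r) <= threshold) next
      edges[[length(edges) + 1L]] <-
        data.frame(a = vars[i], b = vars[j], rho = r,
                   sign = if (r > 0) "positive" else "negative")
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(a = character(), b = character(), rho = numeric(),
               sign = character())
  structure(list(edges = edges, variables = vars, threshold = threshold,
                 rho = rho),
            class = "icg_network")
}

#' @export
print.icg_network <- function(x, ...) {
  cat(sprintf("<icg_network> %d variables, %d edges (|rho| > %.2f)\n",
              length(x$variables), nrow(x$edges), x$threshold))
  if (nrow(x$edges)) print(x$edges, row.names = FALSE)
  invisible(x)
}

#' Convert a correlation network to an igraph object
#'
#' @param network An [build_network()] result.
#' @return An undirected `igraph` graph with edge attributes `rho` and
#'   `sign` and all variables as vertices (isolated ones included).
#' @export
network_igraph <- function(network) {
  stopifnot(inherits(network, "icg_network"))
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = data.frame(name = network$variables))
}

#' Write a correlation network as GraphML
#'
#' @param network An [build_network()] result.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Write the edge list as CSV
#'
#' @param network An [build_network()] result.
#' @param path Output CSV path (columns `a,b,rho,sign`).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  utils::write.csv(network$edges, path, row.names = FALSE)
  invisible(path)
}

#' Plot a correlation heatmap
#'
#' Symmetric-scale heatmap of the Spearman matrix (blue negative, red
#' positive), via pheatmap.
#'
#' @param x An [spearman_matrix()] result or a correlation matrix.
#' @param file Optional output file (`.png` or `.pdf`); `NULL` draws to
#'   the active device.
#' @param ... Passed to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
plot_correlation_heatmap <- function(x, file = NA, ...) {
  rho <- if (inherits(x, "icg_spearman")) x$rho else as.matrix(x)
  rho_plot <- rho
  rho_plot[is.na(rho_plot)] <- 0
  ph <- pheatmap::pheatmap(rho_plot,
                           breaks = seq(-1, 1, length.out = 101),
                           color = grDevices::colorRampPalette(
                             c("#2166AC", "white", "#B2182B"))(100),
                           filename = file, silent = !is.na(file), ...)
  invisible(ph)
}

#' Plot the thresholded correlation network
#'
#' Positive edges blue, negative edges red, edge width proportional to
#' |rho|.
#'
#' @param network An [build_network()] result.
#' @param file Optional PNG path; `NULL` draws to the active device.
#' @param seed Layout seed for reproducibility.
#' @return The igraph object, invisibly.
#' @export
plot_network <- function(network, file = NULL, seed = 1) {
  g <- network_igraph(network)
  cols <- ifelse(igraph::E(g)$sign == "positive", "#2166AC", "#B2182B")
  if (!is.null(file)) grDevices::png(file, width = 900, height = 900)
  set.seed(seed)
  plot(g, edge.color = cols,
       edge.width = 1 + 4 * abs(igraph::E(g)$rho),
       vertex.color = "grey85", vertex.label.color = "black")
  if (!is.null(file)) grDevices::dev.off()
  invisible(g)
}
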