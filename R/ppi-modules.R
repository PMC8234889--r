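#' Build an undirected network from an edge table
#'
#' Self-loops and duplicate edges are removed. `read_edge_list()` reads a
#' two-column TSV (comment lines start with `#`).
#'
#' @param edges Data frame whose first two columns are node IDs.
#' @param path Path to a two-column TSV edge list.
#' @return An [igraph][igraph::graph_from_data_frame] undirected graph.
#' @export
as_network <- function(edges) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
  igraph::simplify(g)
}

#' @rdname as_network
#' @export
read_edge_list <- function(path) {
  readr::read_tsv(path, comment = "#", col_names = c("from", "to"),
                  col_types = "cc", progress = FALSE)
}

#' Diffusion kernel of a network
#'
#' Computes `K = expm(-beta * L)` with `L = D - A` the graph Laplacian, via
#' eigendecomposition per connected component (the kernel of a disconnected
#' graph is block diagonal). K is symmetric positive semidefinite with unit
#' row sums, tends to the identity as `beta -> 0`, and measures
#' connectivity-weighted proximity between nodes.
#'
#' @param net An igraph graph (see [as_network()]) or an edge data frame.
#' @param beta Positive diffusion time.
#' @return A node-by-node matrix of class `kernel_matrix` with attributes
#'   `beta` and `component` (component membership).
#' @examples
#' K <- diffusion_kernel(as_network(data.frame(from = "a", to = "b")), beta = 1)
#' K  # diagonal (1 + exp(-2))/2, off-diagonal (1 - exp(-2))/2
#' @export
diffusion_kernel <- function(net, beta = 1) {
  if (is.data.frame(net)) net <- as_network(net)
  stopifnot(inherits(net, "igraph"))
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 0) {
    stop("beta must be a positive number", call. = FALSE)
  }
  nodes <- igraph::V(net)$name
  n <- length(nodes)
  comp <- igraph::components(net)$membership
  K <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (cm in unique(comp)) {
    idx <- which(comp == cm)
    sub <- igraph::induced_subgraph(net, idx)
    A <- as.matrix(igraph::as_adjacency_matrix(sub))
    L <- diag(rowSums(A), nrow(A)) - A
    e <- eigen(L, symmetric = TRUE)
    Kc <- e$vectors %*% (exp(-beta * e$values) * t(e$vectors))
    K[idx, idx] <- (Kc + t(Kc)) / 2
  }
  structure(K, class = c("kernel_matrix", "matrix"),
            beta = beta, component = comp)
}

#' Kernel-induced dissimilarity between nodes
#'
#' The distance in the kernel's feature space,
#' `d_ij = sqrt(K_ii + K_jj - 2 K_ij)`. Node pairs in different connected
#' components (where the kernel carries no diffusion signal) are set to the
#' largest within-component distance plus 1 so they always merge last.
#'
#' @param K A [diffusion_kernel()] matrix.
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
kernel_dissimilarity <- function(K) {
  stopifnot(is.matrix(K), isSymmetric(unclass(K), tol = 1e-8))
  dg <- diag(K)
  d2 <- outer(dg, dg, "+") - 2 * unclass(K)
  d <- sqrt(pmax(d2, 0))
  diag(d) <- 0
  comp <- attr(K, "component")
  if (!is.null(comp) && length(unique(comp)) > 1) {
    cross <- outer(comp, comp, "!=")
    d[cross] <- max(d[!cross]) + 1
  }
  d
}

#' Hierarchical tree from a dissimilarity matrix
#'
#' Agglomerative clustering of the kernel dissimilarities. Ward linkage
#' (`ward.D2`) is the default: on diffusion-kernel distances, average
#' linkage chains badly — high-degree nodes have inflated self-similarity
#' `K_ii`, which spreads the module cores apart and lets single outlying
#' nodes absorb the whole tree — while Ward's variance criterion recovers
#' planted communities reliably. Average linkage remains available for
#' separable geometries.
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal.
#' @param method `"ward"` (default) or `"average"`.
#' @return An [stats::hclust] tree.
#' @export
hierarchical_tree <- function(d, method = c("ward", "average")) {
  method <- match.arg(method)
  stopifnot(is.matrix(d), isSymmetric(unclass(d), tol = 1e-8),
            all(abs(diag(d)) < 1e-12), all(d >= 0))
  stats::hclust(stats::as.dist(d),
                method = if (method == "ward") "ward.D2" else "average")
}

#' Dynamic tree cut: adaptive branch decomposition with a minimum size
#'
#' Cuts the dendrogram at the midpoint of the largest gap in its merge
#' heights — the height band where the tree's branch structure is most
#' clearly separated — and keeps every resulting branch with at least
#' `min_size` leaves as a module. Leaves in smaller branches stay
#' unassigned. Module labels are deterministic: ordered by decreasing size,
#' ties broken by the alphabetically smallest member, so the result does
#' not depend on input order.
#'
#' @param tree An [stats::hclust] tree (see [hierarchical_tree()]).
#' @param min_size Minimum module size (>= 2); conventionally 5, raised to
#'   25 for very large gene sets.
#' @return Tibble of class `module_set`: `gene_id`, `module` (`"M1"`, ...
#'   or `NA` for unassigned), with attributes `min_size` and `cut_height`.
#' @export
dynamic_tree_cut <- function(tree, min_size = 5) {
  stopifnot(inherits(tree, "hclust"))
  if (min_size < 2) stop("min_size must be >= 2", call. = FALSE)
  n <- length(tree$labels)
  if (min_size > n) {
    warning("min_size (", min_size, ") exceeds leaf count (", n,
            "): all leaves unassigned", call. = FALSE)
    out <- tibble::tibble(gene_id = tree$labels, module = NA_character_)
    class(out) <- c("module_set", class(out))
    attr(out, "min_size") <- min_size
    return(out)
  }
  h <- sort(unique(tree$height))
  if (length(h) == 1) {
    cut_h <- h / 2
  } else {
    gaps <- diff(h)
    i <- which.max(gaps)
    cut_h <- (h[i] + h[i + 1]) / 2
  }
  cl <- stats::cutree(tree, h = cut_h)

  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_size]
  module <- rep(NA_character_, n)
  if (length(keep) > 0) {
    firsts <- vapply(keep, function(k) min(tree$labels[cl == k]), "")
    ord <- keep[order(-as.integer(sizes[keep]), firsts)]
    for (j in seq_along(ord)) {
      module[cl == ord[j]] <- paste0("M", j)
    }
  }
  out <- tibble::tibble(gene_id = tree$labels, module = module)
  out <- dplyr::arrange(out, .data$gene_id)
  class(out) <- c("module_set", class(out))
  attr(out, "min_size") <- min_size
  attr(out, "cut_height") <- cut_h
  out
}

#' Detect network modules among a set of genes
#'
#' Convenience wrapper chaining [diffusion_kernel()],
#' [kernel_dissimilarity()], [hierarchical_tree()] and
#' [dynamic_tree_cut()], restricted to `genes` (e.g., the aging-related
#' transcripts mapped onto the interaction network).
#'
#' @param net igraph network or edge data frame.
#' @param genes Gene IDs to cluster; those absent from the network are
#'   dropped with a message. `NULL` clusters all nodes.
#' @param beta Diffusion parameter.
#' @param min_size Minimum module size.
#' @param method Linkage for [hierarchical_tree()].
#' @return A `module_set` tibble (see [dynamic_tree_cut()]).
#' @export
detect_modules <- function(net, genes = NULL, beta = 1, min_size = 5,
                           method = "ward") {
  if (is.data.frame(net)) net <- as_network(net)
  K <- diffusion_kernel(net, beta = beta)
  if (!is.null(genes)) {
    absent <- setdiff(genes, rownames(K))
    if (length(absent) > 0) {
      message(length(absent), " gene(s) not in the network dropped")
    }
    genes <- intersect(genes, rownames(K))
    if (length(genes) < 3) stop("fewer than 3 genes mapped to the network",
                                call. = FALSE)
    comp <- attr(K, "component")[match(genes, rownames(K))]
    K <- structure(unclass(K)[genes, genes, drop = FALSE],
                   class = c("kernel_matrix", "matrix"),
                   beta = beta, component = comp)
  }
  d <- kernel_dissimilarity(K)
  dynamic_tree_cut(hierarchical_tree(d, method = method),
                   min_size = min_size)
}

#' Survival screen of network modules
#'
#' For each module and each direction (increasing / decreasing with age),
#' builds the expression index of the module's members with that direction
#' ([compute_index()]) and fits a univariate Cox model against survival.
#'
#' @param modules A `module_set` tibble.
#' @param aging An `aging_result` tibble carrying the `direction` calls.
#' @param expr Wide expression tibble (normal tissue).
#' @param clinical Clinical data frame (`time_days`/`time`, `event`).
#' @param mode Index mode passed to [compute_index()].
#' @return Tibble: `module`, `direction`, `n_genes`, `hazard_ratio`,
#'   `p_value`.
#' @export
module_survival_screen <- function(modules, aging, expr, clinical,
                                   mode = "zscore") {
  stopifnot(inherits(modules, "module_set"))
  labs <- sort(unique(stats::na.omit(modules$module)))
  grid <- tidyr::expand_grid(module = labs,
                             direction = c("increasing", "decreasing"))
  purrr::pmap_dfr(grid, function(module, direction) {
    genes <- intersect(modules$gene_id[!is.na(modules$module) &
                                         modules$module == module],
                       aging$gene_id[aging$direction == direction])
    genes <- intersect(genes, expr$gene_id)
    if (length(genes) == 0) return(NULL)
    idx <- compute_index(expr, genes, mode = mode)
    idx <- idx$index[match(sample_order(clinical), idx$sample_id)]
    fit <- tryCatch(
      fit_cox_univariate(clinical, idx, term = paste(module, direction)),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    tibble::tibble(module = module, direction = direction,
                   n_genes = length(genes),
                   hazard_ratio = fit$hr, p_value = fit$p_value)
  })
}

sample_order <- function(clinical) {
  if ("sample_id" %in% names(clinical)) clinical$sample_id
  else stop("clinical table needs a sample_id column", call. = FALSE)
}
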