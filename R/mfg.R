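#' Split signed fluxes onto unidirectional nodes
#'
#' Maps every nonzero flux onto a direction-tagged node: `id_fwd` for
#' positive flux, `id_rev` for negative flux (with the magnitude as the
#' node flux). Zero fluxes are dropped. Total absolute flux is
#' conserved.
#'
#' @param model a `metabolic_model`.
#' @param flux_vector named flux vector over the model's reactions.
#' @param tol magnitude below which a flux counts as zero.
#' @return named nonnegative vector over unidirectional nodes.
#' @export
split_reversible <- function(model, flux_vector, tol = 1e-9) {
  flux_vector <- flux_vector[names(flux_vector) %in% names(model$reactions)]
  keep <- abs(flux_vector) > tol
  v <- flux_vector[keep]
  stats::setNames(abs(v),
                  paste0(names(v), ifelse(v > 0, "_fwd", "_rev")))
}

#' Build a mass flow graph from one flux vector
#'
#' Nodes are unidirectional reactions; a directed edge i -> j carries
#' the mass of each metabolite produced by i and consumed by j,
#' apportioned by j's share of total consumption:
#' \deqn{w_{ij} = \sum_m p_i(m)\, c_j(m) / P(m)}
#' where \eqn{p_i(m)} is i's production rate of m, \eqn{c_j(m)} j's
#' consumption rate, and \eqn{P(m)} the total production. Metabolites
#' with production below `tol` contribute no edges. All metabolites,
#' including currency metabolites, participate unless excluded.
#'
#' @param model a `metabolic_model`.
#' @param flux_vector named flux vector (steady state).
#' @param exclude_metabolites optional metabolite ids to leave out of
#'   the mass flows (e.g. water or protons); none by default.
#' @param tol numeric tolerance for zero production.
#' @return object of class `mass_flow_graph`: list with `nodes`,
#'   `edges` (data frame `from`, `to`, `weight`), and the per-node flux.
#' @export
build_mfg <- function(model, flux_vector, exclude_metabolites = character(0),
                      tol = 1e-9) {
  uni <- split_reversible(model, flux_vector, tol)
  nodes <- names(uni)
  base <- sub("_(fwd|rev)$", "", nodes)
  dirn <- ifelse(grepl("_fwd$", nodes), 1, -1)
  mets <- setdiff(model$metabolites$id, exclude_metabolites)
  prod_list <- list(); cons_list <- list()
  for (k in seq_along(nodes)) {
    st <- model$reactions[[base[k]]]$stoichiometry * dirn[k]
    st <- st[names(st) %in% mets]
    rates <- st * uni[[k]]
    p <- rates[rates > tol]; cns <- -rates[rates < -tol]
    for (m in names(p)) prod_list[[m]] <- c(prod_list[[m]], stats::setNames(p[[m]], nodes[k]))
    for (m in names(cns)) cons_list[[m]] <- c(cons_list[[m]], stats::setNames(cns[[m]], nodes[k]))
  }
  from <- character(0); to <- character(0); w <- numeric(0)
  for (m in names(prod_list)) {
    P <- sum(prod_list[[m]])
    if (P <= tol || is.null(cons_list[[m]])) next
    cons <- cons_list[[m]]
    for (i in names(prod_list[[m]])) {
      share <- prod_list[[m]][[i]] / P
      from <- c(from, rep(i, length(cons)))
      to <- c(to, names(cons))
      w <- c(w, share * cons)
    }
  }
  edges <- data.frame(from = from, to = to, weight = w,
                      stringsAsFactors = FALSE)
  if (nrow(edges)) {
    edges <- stats::aggregate(weight ~ from + to, data = edges, FUN = sum)
    edges <- edges[edges$weight > tol, , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges, node_flux = uni),
            class = "mass_flow_graph")
}

#' @export
print.mass_flow_graph <- function(x, ...) {
  cat("<mass_flow_graph> ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Export a mass flow graph
#'
#' @param graph a `mass_flow_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mfg_edgelist <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_mfg_edgelist
#' @export
write_mfg_graphml <- function(graph, path) {
  root <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  xml2::xml_add_child(root, "key", id = "w", `for` = "edge",
                      attr.name = "weight", attr.type = "double")
  g <- xml2::xml_add_child(root, "graph", id = "mfg", edgedefault = "directed")
  for (n in graph$nodes) xml2::xml_add_child(g, "node", id = n)
  for (i in seq_len(nrow(graph$edges))) {
    e <- xml2::xml_add_child(g, "edge", source = graph$edges$from[i],
                             target = graph$edges$to[i])
    d <- xml2::xml_add_child(e, "data", key = "w")
    xml2::xml_text(d) <- format(graph$edges$weight[i], digits = 12)
  }
  xml2::write_xml(root, path)
  invisible(path)
}

#' PageRank centrality of a mass flow graph
#'
#' Weighted PageRank by power iteration on the column-stochastic
#' transition matrix (edge weights normalized by the source node's total
#' outgoing weight). Dangling nodes redistribute uniformly. Iteration
#' stops when the L1 change falls below `tol`.
#'
#' @param graph a `mass_flow_graph`.
#' @param damping damping factor (default 0.85).
#' @param tol L1 convergence tolerance (default 1e-10).
#' @param max_iter iteration cap; exceeding it is an error reporting the
#'   residual.
#' @return data frame with columns `node`, `pagerank` (summing to 1),
#'   ordered by decreasing score; the damping factor is attached as an
#'   attribute.
#' @export
pagerank_centrality <- function(graph, damping = 0.85, tol = 1e-10,
                                max_iter = 10000L) {
  nodes <- graph$nodes
  n <- length(nodes)
  if (!n) stop("empty graph")
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(graph$edges)) {
    W[cbind(graph$edges$to, graph$edges$from)] <- graph$edges$weight
  }
  outw <- colSums(W)
  dangling <- outw <= 0
  Wn <- W
  if (any(!dangling)) {
    Wn[, !dangling] <- sweep(W[, !dangling, drop = FALSE], 2,
                             outw[!dangling], `/`)
  }
  p <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    pn <- damping * (Wn %*% p + sum(p[dangling]) / n) + (1 - damping) / n
    pn <- as.vector(pn)
    if (sum(abs(pn - p)) < tol) {
      out <- data.frame(node = nodes, pagerank = pn / sum(pn))
      out <- out[order(-out$pagerank), , drop = FALSE]
      rownames(out) <- NULL
      attr(out, "damping") <- damping
      return(out)
    }
    p <- pn
  }
  stop("PageRank power iteration did not converge within ", max_iter,
       " iterations (residual ", format(sum(abs(pn - p))), ")")
}

#' PageRank score distributions over a sample set
#'
#' Builds one mass flow graph and PageRank vector per sampled flux
#' vector, aggregates directional node scores per base reaction, and
#' selects the `top_k` reactions by median score.
#'
#' @param model a `metabolic_model`.
#' @param sample_set a `flux_sample_set`.
#' @param top_k number of top reactions to report (default 17).
#' @param rows optional subset of sample rows to use.
#' @param damping damping factor (default 0.85).
#' @param exclude_metabolites forwarded to [build_mfg()].
#' @return list with `scores` (rows = samples, columns = reactions;
#'   a reaction inactive in a sample scores 0), `medians`, `top`
#'   (character vector of the top reactions), `failed_rows`.
#' @export
centrality_over_samples <- function(model, sample_set, top_k = 17,
                                    rows = NULL, damping = 0.85,
                                    exclude_metabolites = character(0)) {
  X <- sample_set$samples
  if (is.null(rows)) rows <- seq_len(nrow(X))
  rxns <- sample_set$reactions
  scores <- matrix(0, length(rows), length(rxns),
                   dimnames = list(NULL, rxns))
  failed <- integer(0)
  for (k in seq_along(rows)) {
    res <- tryCatch({
      g <- build_mfg(model, X[rows[k], ],
                     exclude_metabolites = exclude_metabolites)
      pagerank_centrality(g, damping = damping)
    }, error = function(e) NULL)
    if (is.null(res)) { failed <- c(failed, rows[k]); next }
    base <- sub("_(fwd|rev)$", "", res$node)
    agg <- tapply(res$pagerank, base, sum)
    scores[k, names(agg)] <- agg
  }
  med <- apply(scores, 2, stats::median)
  top <- names(sort(med, decreasing = TRUE))[seq_len(min(top_k, length(med)))]
  list(scores = scores, medians = med, top = top, failed_rows = failed)
}
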