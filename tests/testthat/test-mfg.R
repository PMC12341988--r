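test_that("reversible splitting conserves absolute flux", {
  m <- toy_split_model()
  v <- c(SRC = 10, F = 2, T = -3, SINK = 0)
  u <- split_reversible(m, v)
  expect_equal(u[["F_fwd"]], 2)
  expect_equal(u[["T_rev"]], 3)
  expect_false(any(grepl("SINK", names(u))))
  expect_equal(sum(u), sum(abs(v)))
})

test_that("edge weights follow the flow-splitting formula", {
  ## R1 produces m at rate 2; R2 consumes 1.5, R3 consumes 0.5
  mets <- data.frame(id = c("x_c", "m_c"), name = c("x", "m"),
                     compartment = "c", formula = c("C", "C"), charge = 0)
  rxns <- list(
    list(id = "R1", stoichiometry = c(x_c = -1, m_c = 1), lb = 0, ub = 10,
         gene_rule = "", subsystem = ""),
    list(id = "EX_x", stoichiometry = c(x_c = 1), lb = 0, ub = 10,
         gene_rule = "", subsystem = ""),
    list(id = "R2", stoichiometry = c(m_c = -1), lb = 0, ub = 10,
         gene_rule = "", subsystem = ""),
    list(id = "R3", stoichiometry = c(m_c = -1), lb = 0, ub = 10,
         gene_rule = "", subsystem = ""))
  m <- metabolic_model("toy", mets, rxns, "R1", c(c = "cytosol"))
  g <- build_mfg(m, c(R1 = 2, EX_x = 2, R2 = 1.5, R3 = 0.5))
  e <- g$edges
  expect_equal(e$weight[e$from == "R1_fwd" & e$to == "R2_fwd"], 1.5)
  expect_equal(e$weight[e$from == "R1_fwd" & e$to == "R3_fwd"], 0.5)
  ## zero flux vector: no nodes, no edges
  g0 <- build_mfg(m, c(R1 = 0, EX_x = 0, R2 = 0, R3 = 0))
  expect_length(g0$nodes, 0)
  expect_equal(nrow(g0$edges), 0L)
})

test_that("edge weights and flow conservation hold on real flux vectors", {
  m <- mini_model()
  sol <- solve_fba(m, mini_condition("ch4"), solver_settings(parsimonious = TRUE))
  v <- sol$fluxes
  g <- build_mfg(m, v)
  want <- mfg_weight_oracle(m, v)
  got <- stats::setNames(g$edges$weight,
                         paste(g$edges$from, g$edges$to, sep = "->"))
  expect_setequal(names(got), names(want))
  expect_equal(got[names(want)], want, tolerance = 1e-8)
  ## conservation: each producer's outgoing flow through a metabolite
  ## equals its production of it, so summed over metabolites the total
  ## edge weight out of node i equals its total (consumed) production
  uni <- g$node_flux
  base <- sub("_(fwd|rev)$", "", names(uni))
  dirn <- ifelse(grepl("_fwd$", names(uni)), 1, -1)
  for (i in seq_along(uni)) {
    st <- m$reactions[[base[i]]]$stoichiometry * dirn[i]
    prod_i <- 0
    for (met in names(st)[st > 0]) {
      ## count only production that is actually consumed by some reaction
      consumed <- any(vapply(seq_along(uni), function(k) {
        sk <- m$reactions[[base[k]]]$stoichiometry * dirn[k]
        met %in% names(sk) && sk[[met]] < -1e-9
      }, logical(1)))
      if (consumed) prod_i <- prod_i + st[[met]] * uni[[i]]
    }
    out_i <- sum(g$edges$weight[g$edges$from == names(uni)[i]])
    expect_equal(out_i, prod_i, tolerance = 1e-6)
  }
})

test_that("PageRank matches symmetry, eigen-oracle, and igraph", {
  ## single node
  g1 <- structure(list(nodes = "A",
                       edges = data.frame(from = character(0),
                                          to = character(0),
                                          weight = numeric(0)),
                       node_flux = c(A = 1)), class = "mass_flow_graph")
  expect_equal(pagerank_centrality(g1)$pagerank, 1)
  ## two-node symmetric cycle
  g2 <- structure(list(nodes = c("A", "B"),
                       edges = data.frame(from = c("A", "B"), to = c("B", "A"),
                                          weight = c(2, 2)),
                       node_flux = c(A = 1, B = 1)), class = "mass_flow_graph")
  expect_equal(pagerank_centrality(g2)$pagerank, c(0.5, 0.5), tolerance = 1e-9)
  ## 5-node weighted toy with a dangling node
  set.seed(12)
  nodes <- LETTERS[1:5]
  edges <- data.frame(from = c("A", "A", "B", "C", "D", "C"),
                      to   = c("B", "C", "C", "D", "A", "A"),
                      weight = c(1, 2, 3, 0.5, 1.5, 0.25))
  g5 <- structure(list(nodes = nodes, edges = edges,
                       node_flux = stats::setNames(rep(1, 5), nodes)),
                  class = "mass_flow_graph")
  got <- pagerank_centrality(g5)
  want <- pagerank_eigen_oracle(g5)
  expect_equal(stats::setNames(got$pagerank, got$node)[names(want)],
               want, tolerance = 1e-8)
  expect_equal(sum(got$pagerank), 1, tolerance = 1e-9)
  if (requireNamespace("igraph", quietly = TRUE)) {
    ig <- igraph::graph_from_data_frame(edges, vertices = nodes)
    ip <- igraph::page_rank(ig, weights = edges$weight, damping = 0.85)$vector
    expect_equal(stats::setNames(got$pagerank, got$node)[names(ip)],
                 ip, tolerance = 1e-6)
  }
  ## invariance under uniform edge-weight rescaling
  g5b <- g5; g5b$edges$weight <- g5$edges$weight * 13
  expect_equal(pagerank_centrality(g5b)$pagerank, got$pagerank,
               tolerance = 1e-9)
})

test_that("graph construction is invariant to reaction order", {
  m <- mini_model()
  sol <- solve_fba(m, mini_condition("ch4"), solver_settings(parsimonious = TRUE))
  v <- sol$fluxes
  g1 <- build_mfg(m, v)
  m2 <- m
  set.seed(2)
  m2$reactions <- m2$reactions[sample(length(m2$reactions))]
  g2 <- build_mfg(m2, v[names(m2$reactions)])
  key <- function(g) {
    e <- g$edges[order(g$edges$from, g$edges$to), ]
    rownames(e) <- NULL
    e
  }
  expect_equal(key(g1), key(g2), tolerance = 1e-12)
})

test_that("centrality over samples ranks the electron transport chain on top", {
  m <- mini_model()
  ss <- sample_fluxes(m, mini_condition("ch4"), n_samples = 60, seed = 17,
                      thinning = 10)
  co <- centrality_over_samples(m, ss, top_k = 8)
  expect_length(co$failed_rows, 0)
  etc <- c("NADH16pp", "CYTCBB3pp1", "ATPS4rpp")
  expect_true(all(etc %in% co$top))
  ## identical samples give zero-variance scores
  ss2 <- ss; ss2$samples <- ss$samples[rep(1, 10), ]
  co2 <- centrality_over_samples(m, ss2)
  expect_true(all(apply(co2$scores, 2, stats::sd) < 1e-12))
  ## medians equal brute-force recomputation on a 10-row subset
  co3 <- centrality_over_samples(m, ss, rows = 1:10)
  manual <- sapply(1:10, function(k) {
    pr <- pagerank_centrality(build_mfg(m, ss$samples[k, ]))
    agg <- tapply(pr$pagerank, sub("_(fwd|rev)$", "", pr$node), sum)
    full <- stats::setNames(numeric(length(ss$reactions)), ss$reactions)
    full[names(agg)] <- agg
    full
  })
  expect_equal(unname(co3$medians), unname(apply(manual, 1, stats::median)),
               tolerance = 1e-10)
})
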