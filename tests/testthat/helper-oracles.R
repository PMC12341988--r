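## Shared fixtures and independent oracles.

`%||%` <- function(a, b) if (is.null(a)) b else a

## cache the (deterministic) mini-model and standard conditions so each
## test file pays the construction cost once
.cache <- new.env(parent = emptyenv())
mini_model <- function() {
  if (is.null(.cache$model)) .cache$model <- build_minimodel()
  .cache$model
}
mini_condition <- function(substrate = "ch4", ...) {
  key <- paste0("cond_", substrate, "_", paste(c(...), collapse = "_"))
  if (is.null(.cache[[key]])) {
    .cache[[key]] <- build_condition(substrate, model = mini_model(), ...)
  }
  .cache[[key]]
}

## Brute-force LP oracle: enumerate every basic solution (choice of m
## basic columns, nonbasic variables at each bound combination) of
##   max c'x  s.t.  A x = b, lb <= x <= ub
## Exact for tiny instances; completely independent of the simplex code.
brute_force_lp <- function(obj, A, b, lb, ub) {
  n <- ncol(A); m <- nrow(A)
  best <- -Inf; best_x <- NULL; feasible <- FALSE
  nb_combos <- function(k) {
    if (k == 0) return(matrix(numeric(0), 1, 0))
    grid <- as.matrix(expand.grid(rep(list(c(1, 2)), k)))
    grid
  }
  if (m == 0) {
    x <- ifelse(abs(obj) < 1e-15, lb, ifelse(obj > 0, ub, lb))
    return(list(objective = sum(obj * x), x = x, feasible = TRUE))
  }
  for (basis in utils::combn(n, m, simplify = FALSE)) {
    B <- A[, basis, drop = FALSE]
    if (abs(det(B)) < 1e-10) next
    nonbasis <- setdiff(seq_len(n), basis)
    combos <- nb_combos(length(nonbasis))
    for (ci in seq_len(nrow(combos))) {
      x <- numeric(n)
      if (length(nonbasis)) {
        x[nonbasis] <- ifelse(combos[ci, ] == 1, lb[nonbasis], ub[nonbasis])
      }
      xb <- solve(B, b - A[, nonbasis, drop = FALSE] %*% x[nonbasis])
      x[basis] <- xb
      if (any(x < lb - 1e-8) || any(x > ub + 1e-8)) next
      feasible <- TRUE
      val <- sum(obj * x)
      if (val > best + 1e-12) { best <- val; best_x <- x }
    }
  }
  list(objective = best, x = best_x, feasible = feasible)
}

## random tiny metabolic-style LP instances (integer stoichiometry,
## mixed reversibility) used for oracle-equality checks
random_tiny_lp <- function(seed) {
  set.seed(seed)
  m <- sample(2:3, 1); n <- m + sample(2:4, 1)
  repeat {
    A <- matrix(sample(c(-2, -1, 0, 1, 2), m * n, TRUE,
                       prob = c(.1, .3, .2, .3, .1)), m, n)
    if (all(rowSums(A != 0) > 0)) break
  }
  lb <- ifelse(stats::runif(n) < 0.4, -5, 0)
  ub <- rep(5, n)
  obj <- round(stats::rnorm(n), 1)
  list(obj = obj, A = A, b = rep(0, m), lb = lb, ub = ub)
}

## quadratic-time KS oracle: evaluate both ECDFs at every pooled point
brute_force_ks <- function(x, y) {
  pts <- c(x, y)
  d <- 0
  for (p in pts) {
    d <- max(d, abs(sum(x <= p) / length(x) - sum(y <= p) / length(y)))
  }
  d
}

## dense eigen-solve oracle for PageRank: dominant eigenvector of the
## Google matrix G = d (W D^-1 + u 1'_dangling) + (1-d) u 1'
pagerank_eigen_oracle <- function(graph, damping = 0.85) {
  nodes <- graph$nodes; n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(graph$edges)) {
    W[cbind(graph$edges$to, graph$edges$from)] <- graph$edges$weight
  }
  outw <- colSums(W)
  M <- matrix(0, n, n)
  for (j in seq_len(n)) {
    M[, j] <- if (outw[j] > 0) W[, j] / outw[j] else rep(1 / n, n)
  }
  G <- damping * M + (1 - damping) / n
  ev <- eigen(G)
  k <- which.max(abs(Re(ev$values)))
  v <- abs(Re(ev$vectors[, k]))
  stats::setNames(v / sum(v), nodes)
}

## independent recomputation of every mass-flow-graph edge weight by
## looping over metabolites (the implementation loops over reactions)
mfg_weight_oracle <- function(model, v, tol = 1e-9) {
  uni <- split_reversible(model, v, tol)
  base <- sub("_(fwd|rev)$", "", names(uni))
  dirn <- ifelse(grepl("_fwd$", names(uni)), 1, -1)
  W <- list()
  for (met in metabolite_ids(model)) {
    prod <- numeric(0); cons <- numeric(0)
    for (k in seq_along(uni)) {
      st <- model$reactions[[base[k]]]$stoichiometry * dirn[k]
      if (!met %in% names(st)) next
      r <- st[[met]] * uni[[k]]
      if (r > tol) prod[names(uni)[k]] <- r
      if (r < -tol) cons[names(uni)[k]] <- -r
    }
    P <- sum(prod)
    if (P <= tol || !length(cons)) next
    for (i in names(prod)) for (j in names(cons)) {
      key <- paste(i, j, sep = "->")
      W[[key]] <- (W[[key]] %||% 0) + prod[[i]] * cons[[j]] / P
    }
  }
  unlist(W)
}

## hand-built toy models ------------------------------------------------

## linear chain EX_in -> (a) -> R1 -> (b) -> EX_out with unit coefficients
toy_chain_model <- function(input_ub = 1) {
  mets <- data.frame(id = c("a_c", "b_c"), name = c("a", "b"),
                     compartment = "c", formula = c("C", "C"), charge = 0)
  rxns <- list(
    list(id = "EX_a", stoichiometry = c(a_c = 1), lb = 0, ub = input_ub,
         gene_rule = "", subsystem = "Exchange"),
    list(id = "R1", stoichiometry = c(a_c = -1, b_c = 1), lb = 0, ub = 1000,
         gene_rule = "g1", subsystem = "chain"),
    list(id = "EX_b", stoichiometry = c(b_c = -1), lb = 0, ub = 1000,
         gene_rule = "", subsystem = "Exchange"))
  metabolic_model("chain", mets, rxns, objective_id = "EX_b",
                  compartments = c(c = "cytosol"))
}

## source splitting into two parallel branches F and T that rejoin
toy_split_model <- function(source_flux = 10) {
  mets <- data.frame(id = c("s_c", "p_c"), name = c("s", "p"),
                     compartment = "c", formula = c("C", "C"), charge = 0)
  rxns <- list(
    list(id = "SRC", stoichiometry = c(s_c = 1), lb = source_flux,
         ub = source_flux, gene_rule = "", subsystem = "Exchange"),
    list(id = "F", stoichiometry = c(s_c = -1, p_c = 1), lb = 0, ub = 1000,
         gene_rule = "", subsystem = "branch"),
    list(id = "T", stoichiometry = c(s_c = -1, p_c = 1), lb = 0, ub = 1000,
         gene_rule = "", subsystem = "branch"),
    list(id = "SINK", stoichiometry = c(p_c = -1), lb = 0, ub = 1000,
         gene_rule = "", subsystem = "Exchange"))
  metabolic_model("split", mets, rxns, objective_id = "SINK",
                  compartments = c(c = "cytosol"))
}

## toy models for energy-generating-cycle detection; `broken = TRUE`
## adds a cost-free ADP + Pi -> ATP reaction closing an EGC
toy_energy_model <- function(broken = FALSE, reversible_atpase = FALSE) {
  mets <- data.frame(
    id = c("atp_c", "adp_c", "pi_c", "h2o_c", "h_c", "glc_c"),
    name = c("ATP", "ADP", "Pi", "water", "proton", "fuel"),
    compartment = "c",
    formula = c("C10H12N5O13P3", "C10H12N5O10P2", "HO4P", "H2O", "H", "C6H12O6"),
    charge = c(-4, -3, -2, 0, 1, 0))
  rxns <- list(
    list(id = "EX_glc", stoichiometry = c(glc_c = 1), lb = 0, ub = 10,
         gene_rule = "", subsystem = "Exchange"),
    list(id = "FUEL", stoichiometry = c(glc_c = -1, adp_c = -2, pi_c = -2,
                                        h_c = -2, atp_c = 2, h2o_c = 2),
         lb = 0, ub = 1000, gene_rule = "", subsystem = "energy"),
    list(id = "ATPASE",
         stoichiometry = c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
         lb = if (reversible_atpase) -1000 else 0, ub = 1000,
         gene_rule = "", subsystem = "energy"),
    list(id = "EX_h2o", stoichiometry = c(h2o_c = -1), lb = -1000, ub = 1000,
         gene_rule = "", subsystem = "Exchange"))
  if (broken) {
    rxns <- c(rxns, list(list(
      id = "FREE_ATP",
      stoichiometry = c(adp_c = -1, pi_c = -1, h_c = -1, atp_c = 1, h2o_c = 1),
      lb = 0, ub = 1000, gene_rule = "", subsystem = "broken")))
  }
  metabolic_model("energy_toy", mets, rxns, objective_id = "ATPASE",
                  compartments = c(c = "cytosol"))
}
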