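# Independent oracles, deliberately written against the C++ kernel's grain:
# vectorized base-R energy computation and an igraph flood fill over sites.

ref_total_energy <- function(sys) {
  lab <- sys$labels
  W <- nrow(lab); H <- ncol(lab)
  p <- sys$params
  types <- c(0L, as.integer(sys$cells$type)) # index = label + 1
  tmat <- matrix(types[lab + 1L], W, H)
  C <- pottsort:::field_matrix(sys$field)
  pair_e <- function(sa, sb, ta, tb)
    sum((as.vector(sa) != as.vector(sb)) *
          p$J[cbind(as.vector(ta) + 1, as.vector(tb) + 1)])
  E <- pair_e(lab[-W, ], lab[-1, ], tmat[-W, ], tmat[-1, ]) +
    pair_e(lab[, -H], lab[, -1], tmat[, -H], tmat[, -1])
  areas <- tabulate(lab[lab > 0], nbins = nrow(sys$cells))
  E <- E + sum(p$lambda * (areas - p$a_target[sys$cells$type])^2)
  occ <- lab > 0
  E - sum(p$mu[tmat[occ]] * C[occ])
}

# Site-level flood fill on type labels (igraph components); equals the
# cell-adjacency cluster count whenever every cell domain is connected,
# e.g. for freshly tiled systems.
flood_fill_clusters <- function(sys) {
  lab <- sys$labels
  W <- nrow(lab); H <- ncol(lab)
  types <- c(0L, as.integer(sys$cells$type))
  tmat <- matrix(types[lab + 1L], W, H)
  idx <- matrix(seq_len(W * H), W, H)
  hor <- cbind(as.vector(idx[-W, ]), as.vector(idx[-1, ]))
  ver <- cbind(as.vector(idx[, -H]), as.vector(idx[, -1]))
  keep_h <- tmat[-W, ] > 0 & tmat[-W, ] == tmat[-1, ]
  keep_v <- tmat[, -H] > 0 & tmat[, -H] == tmat[, -1]
  edges <- rbind(hor[as.vector(keep_h), , drop = FALSE],
                 ver[as.vector(keep_v), , drop = FALSE])
  g <- igraph::make_graph(t(edges), n = W * H, directed = FALSE)
  comp <- igraph::components(g)
  length(unique(comp$membership[as.vector(tmat) > 0]))
}

# small 4-cell fixture with scrambled labels, all four types present
scrambled_fixture <- function(mu0 = 0.8, j = 0.7, n_mcs = 50) {
  g <- grid_spec(2, 2, 6)
  sys <- init_cells(g, potts_params(n_t = 4, mu0 = mu0, j = j), r = 1)
  if (n_mcs > 0) sys <- run_mcs(sys, n_mcs, cadence = 0)$system
  sys
}

zero_field <- function(grid) matrix(0, grid$width, grid$height)
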