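# Independent brute-force oracles, coded separately from the package
# implementation: a plain-loop QM-selection pipeline, an element-wise
# two-electron contraction, and a direct-minimization SCF.

# ----------------------------------------------------- selector oracle --

# Edge list of a system as a plain two-column matrix (0-based).
oracle_edges <- function(system) system$bonds$edges

oracle_neighbors <- function(edges, i) {
  sort(c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1]))
}

# Is edge (i,j) part of a cycle? BFS from i to j avoiding the edge itself.
oracle_in_ring <- function(edges, i, j) {
  seen <- c(i)
  queue <- i
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in oracle_neighbors(edges, u)) {
      if ((u == i && v == j) || (u == j && v == i)) next
      if (v == j) return(TRUE)
      if (!(v %in% seen)) { seen <- c(seen, v); queue <- c(queue, v) }
    }
  }
  FALSE
}

# Keys "i:j" (i < j) of all ring edges, computed once per system.
oracle_ring_keys <- function(edges) {
  keys <- character(0)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    if (oracle_in_ring(edges, i, j)) {
      keys <- c(keys, paste(min(i, j), max(i, j), sep = ":"))
    }
  }
  keys
}

# memoized per call chain via an environment keyed by the edge matrix
.oracle_ring_cache <- new.env(parent = emptyenv())

oracle_rings_of <- function(edges) {
  key <- paste(c(dim(edges), edges), collapse = ",")
  key <- substr(digest_simple(key), 1, 32)
  if (!is.null(.oracle_ring_cache[[key]])) return(.oracle_ring_cache[[key]])
  rk <- oracle_ring_keys(edges)
  .oracle_ring_cache[[key]] <- rk
  rk
}

digest_simple <- function(s) {
  # small deterministic string hash (sum of char codes in blocks)
  v <- utf8ToInt(s)
  paste(sprintf("%x", (cumsum(v * seq_along(v)) %% 2147483647)[
    unique(pmin(length(v), ceiling(seq(1, length(v), length.out = 8))))]),
    collapse = "")
}

# Rule predicate: returns matched description or NA.
oracle_cut_match <- function(system, edges, i, j, rules) {
  a <- system$atoms
  if (a$element[i + 1] != "C" || a$element[j + 1] != "C") return(NA_character_)
  if (paste(min(i, j), max(i, j), sep = ":") %in% oracle_rings_of(edges)) {
    return(NA_character_)
  }
  for (k in seq_len(nrow(rules))) {
    ok <- (a$name[i + 1] == rules$qm_name[k] && a$name[j + 1] == rules$mm_name[k]) ||
          (a$name[i + 1] == rules$mm_name[k] && a$name[j + 1] == rules$qm_name[k])
    if (!ok) next
    if (!is.na(rules$resname[k]) &&
        !(a$resname[i + 1] == rules$resname[k] ||
          a$resname[j + 1] == rules$resname[k])) next
    return(rules$description[k])
  }
  NA_character_
}

# All-pairs radial seeding: heavy atoms within radius of any core atom in
# any frame, plus hydrogen completion to a fixpoint.
oracle_radial <- function(system, core_idx, radius, frame_labels) {
  sel <- core_idx
  heavy <- which(!system$atoms$is_hydrogen) - 1L
  for (fl in frame_labels) {
    xyz <- system$frames[[fl]]
    for (h in heavy) {
      for (c_i in core_idx) {
        d <- sqrt(sum((xyz[h + 1, ] - xyz[c_i + 1, ])^2))
        if (d <= radius) sel <- c(sel, h)
      }
    }
  }
  sel <- sort(unique(sel))
  edges <- oracle_edges(system)
  is_h <- system$atoms$is_hydrogen
  repeat {
    extra <- integer(0)
    for (i in sel) {
      for (j in oracle_neighbors(edges, i)) {
        if (j %in% sel) next
        if ((!is_h[i + 1] && is_h[j + 1]) || (is_h[i + 1] && !is_h[j + 1])) {
          extra <- c(extra, j)
        }
      }
    }
    if (!length(extra)) break
    sel <- sort(unique(c(sel, extra)))
  }
  sel
}

# Closure under bond traversal with the rule predicate.
oracle_closure <- function(system, seed, rules, forbidden = integer(0)) {
  edges <- oracle_edges(system)
  sel <- sort(unique(seed))
  repeat {
    extra <- integer(0)
    for (i in sel) {
      for (j in oracle_neighbors(edges, i)) {
        if (j %in% sel || j %in% forbidden) next
        if (is.na(oracle_cut_match(system, edges, i, j, rules))) {
          extra <- c(extra, j)
        }
      }
    }
    if (!length(extra)) break
    sel <- sort(unique(c(sel, extra)))
  }
  sel
}

oracle_events <- function(system, sel, rules) {
  edges <- oracle_edges(system)
  ev <- data.frame(qm_atom = integer(0), mm_atom = integer(0))
  for (i in sel) {
    for (j in oracle_neighbors(edges, i)) {
      if (j %in% sel) next
      ev <- rbind(ev, data.frame(qm_atom = i, mm_atom = j))
    }
  }
  ev[order(ev$qm_atom, ev$mm_atom), , drop = FALSE]
}

# Fixed-point shared-MM merging by exhaustive re-extension.
oracle_merge <- function(system, sel, rules) {
  repeat {
    ev <- oracle_events(system, sel, rules)
    shared <- sort(unique(ev$mm_atom[duplicated(ev$mm_atom)]))
    if (!length(shared)) return(sel)
    sel <- oracle_closure(system, c(sel, shared[1]), rules)
  }
}

# Component scan pruning of detached small aliphatic islands.
oracle_prune <- function(system, sel, core_idx, max_carbons = 2L) {
  edges <- oracle_edges(system)
  remaining <- sel
  comps <- list()
  while (length(remaining)) {
    comp <- remaining[1]
    repeat {
      grow <- integer(0)
      for (i in comp) {
        nb <- oracle_neighbors(edges, i)
        grow <- c(grow, nb[nb %in% remaining & !(nb %in% comp)])
      }
      if (!length(grow)) break
      comp <- sort(unique(c(comp, grow)))
    }
    comps <- c(comps, list(comp))
    remaining <- setdiff(remaining, comp)
  }
  el <- system$atoms$element
  keep <- integer(0)
  for (comp in comps) {
    heavies <- comp[el[comp + 1] != "H"]
    is_core <- any(core_idx %in% comp)
    aliphatic <- length(heavies) > 0 && all(el[heavies + 1] == "C") &&
      length(heavies) <= max_carbons
    if (is_core || !aliphatic) keep <- c(keep, comp)
  }
  sort(keep)
}

# The composed pipeline.
oracle_select <- function(system, core_idx, radius, frame_labels, rules,
                          max_carbons = 2L) {
  sel <- oracle_radial(system, core_idx, radius, frame_labels)
  sel <- oracle_closure(system, sel, rules)
  sel <- oracle_merge(system, sel, rules)
  oracle_prune(system, sel, core_idx, max_carbons)
}

# ------------------------------------------------------------ SCF oracle --

# Element-wise loop evaluation of the level energy (textbook formula).
oracle_level_energy <- function(H, cx, D) {
  n <- H$n_basis
  e <- H$constant_energy
  for (mu in 1:n) for (nu in 1:n) e <- e + D[mu, nu] * H$core_h[mu, nu]
  for (mu in 1:n) for (nu in 1:n) for (la in 1:n) for (si in 1:n) {
    e <- e + 0.5 * D[mu, nu] * H$two_electron[mu, nu, la, si] * D[la, si] -
      cx * 0.25 * D[mu, la] * H$two_electron[mu, nu, la, si] * D[nu, si]
  }
  e
}

# Direct minimization of the energy over S-orthonormal occupied orbitals,
# parameterized by an unconstrained matrix V -> C = V (V' S V)^{-1/2}.
# Several deterministic starts; returns the lowest energy found.
oracle_scf_energy <- function(H, cx, n_starts = 4) {
  n <- H$n_basis
  nocc <- H$n_electrons %/% 2
  S <- H$overlap
  energy_of <- function(v) {
    V <- matrix(v, n, nocc)
    M <- t(V) %*% S %*% V
    e <- eigen(M, symmetric = TRUE)
    if (min(e$values) < 1e-10) return(1e6)
    Mi <- e$vectors %*% diag(1 / sqrt(e$values), nocc) %*% t(e$vectors)
    C <- V %*% Mi
    D <- 2 * tcrossprod(C)
    # vectorized energy (independent from package: explicit contraction)
    J <- matrix(matrix(H$two_electron, n * n, n * n) %*% as.vector(D), n, n)
    K <- matrix(matrix(aperm(H$two_electron, c(1, 3, 2, 4)),
                       n * n, n * n) %*% as.vector(D), n, n)
    H$constant_energy + sum(D * H$core_h) + 0.5 * sum(D * J) -
      cx * 0.25 * sum(D * K)
  }
  best <- Inf
  ev <- eigen(solve(S, H$core_h))
  starts <- list(Re(ev$vectors[, order(Re(ev$values))[1:nocc]]))
  set.seed(1234)
  for (k in seq_len(n_starts - 1)) {
    starts <- c(starts, list(matrix(rnorm(n * nocc), n, nocc)))
  }
  for (V0 in starts) {
    opt <- stats::optim(as.vector(V0), energy_of, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-15))
    opt <- stats::optim(opt$par, energy_of, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-15))
    best <- min(best, opt$value)
  }
  best
}
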