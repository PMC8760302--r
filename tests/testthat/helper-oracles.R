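# Independent brute-force oracles used across the suite.  These deliberately
# avoid phyper/dhyper/dbinom and the package's own code paths: probabilities
# come from choose()/lchoose() enumeration, graph closure from boolean
# matrix powers.

# Hypergeometric overlap p-value by full enumeration of the 2x2 table
# support.  nq = |query|, nt = |term|, bg = |background|.
oracle_hyper_p <- function(a, nq, nt, bg,
                           alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  lo <- max(0, nq + nt - bg); hi <- min(nq, nt)
  ks <- lo:hi
  probs <- choose(nt, ks) * choose(bg - nt, nq - ks) / choose(bg, nq)
  obs <- probs[ks == a]
  switch(alternative,
         greater = sum(probs[ks >= a]),
         less = sum(probs[ks <= a]),
         two.sided = min(1, sum(probs[probs <= obs * (1 + 1e-7)])))
}

# Binomial two-sided minimum-likelihood p by full pmf enumeration.
oracle_binom_p <- function(x, size, prob,
                           alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  ks <- 0:size
  logpmf <- lchoose(size, ks) + ks * log(prob) + (size - ks) * log1p(-prob)
  pmf <- exp(logpmf)
  switch(alternative,
         greater = sum(pmf[ks >= x]),
         less = sum(pmf[ks <= x]),
         two.sided = min(1, sum(pmf[pmf <= pmf[x + 1] * (1 + 1e-7)])))
}

# Transitive closure of a child->parent edge list by boolean matrix powers.
oracle_ancestors <- function(ids, parents, term) {
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (id in ids) A[id, parents[[id]]] <- TRUE
  closure <- A
  repeat {
    nxt <- closure | (closure %*% A > 0)
    if (identical(nxt, closure)) break
    closure <- nxt
  }
  sort(ids[closure[term, ]])
}

# Random DAG as (ids, parents): each term links to >= 0 earlier terms.
random_dag <- function(n_terms, p_edge = 0.3) {
  ids <- sprintf("T%03d", seq_len(n_terms))
  parents <- stats::setNames(vector("list", n_terms), ids)
  parents[[ids[1]]] <- character(0)
  for (i in seq_len(n_terms)[-1]) {
    sel <- runif(i - 1) < p_edge
    parents[[ids[i]]] <- ids[seq_len(i - 1)][sel]
  }
  list(ids = ids, parents = parents)
}

# Small simulation config used by fast tests; overrides win over the
# reduced-scale defaults.
small_sim_config <- function(seed = 11, ...) {
  base <- list(n_genes = 1200,
               program_sizes = c("early-transient" = 120,
                                 "early-stable" = 110,
                                 "early-increasing" = 80, "late" = 120),
               n_background_stats = 400, n_unexpressed = 60,
               sc_celltypes = c("RG-early" = 30, "RG" = 60, "IPC" = 40,
                                "Transitioning" = 40, "Newborn" = 50,
                                "Developing" = 70),
               n_terms = 30, n_signal_terms = 3, signal_term_size = 60,
               n_samples = 6, seed = seed)
  overrides <- list(...)
  base[names(overrides)] <- overrides
  do.call(sim_config, base)
}
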