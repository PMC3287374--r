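# Shared fixtures and independent oracles for the test suite. Oracles here
# must not call the implementation paths they are used to check.

# Independent soft-polytomy counter: parses the Newick string directly and
# counts "(...)" groups with more than two top-level children.
oracle_count_polytomies <- function(nwk) {
  chars <- strsplit(sub(";\\s*$", "", nwk), "")[[1]]
  stack <- integer(0)          # top-level child count per open group
  count <- 0L
  for (ch in chars) {
    if (ch == "(") {
      stack <- c(stack, 1L)
    } else if (ch == ",") {
      stack[length(stack)] <- stack[length(stack)] + 1L
    } else if (ch == ")") {
      if (stack[length(stack)] > 2L) count <- count + 1L
      stack <- stack[-length(stack)]
    }
  }
  count
}

# Independent Brownian covariance: root-to-MRCA path length for every tip
# pair via ape's node depths and MRCA finder (a different code path from
# phylo_covariance / vcv).
oracle_bm_covariance <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)   # root-to-node distances
  ntip <- length(tree$tip.label)
  M <- ape::mrca(tree)
  V <- matrix(depth[M], ntip, ntip,
              dimnames = list(tree$tip.label, tree$tip.label))
  diag(V) <- depth[seq_len(ntip)]
  V
}

# Independent Hedges' d: the same published formulas typed separately.
oracle_hedges_d <- function(mean_d, sd_d, n_d, mean_c, sd_c, n_c) {
  m <- n_d + n_c - 2
  sp <- sqrt(((n_d - 1) * sd_d^2 + (n_c - 1) * sd_c^2) / m)
  J <- 1 - 3 / (4 * m - 1)
  d <- J * (mean_d - mean_c) / sp
  list(d = d, var_d = (n_d + n_c) / (n_d * n_c) + d^2 / (2 * m))
}

# Independent multivariate-normal log density for the GLS likelihood check.
oracle_mvn_logdensity <- function(y, mu, Sigma) {
  n <- length(y)
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  r <- y - mu
  -n / 2 * log(2 * pi) - ld / 2 -
    as.numeric(t(r) %*% solve(Sigma, r)) / 2
}

# Random topology (no branch lengths) for property tests.
random_topology <- function(n) {
  ape::rtree(n, br = NULL)
}

# A small handmade case table: 4 species, 2 venues, paired treatments for
# three of the four cases.
tiny_cases <- function() {
  mk <- function(cid, sp, risk, venue, treat, pm, mm) {
    data.frame(case_id = cid, species = sp, population = NA_character_,
               risk_group = risk, venue = venue, treatment = treat,
               period_mean = pm, period_sd = 0.1 * pm, period_n = 10,
               mass_mean = mm, mass_sd = 0.15 * mm, mass_n = 10,
               mass_is_volume = FALSE, stringsAsFactors = FALSE)
  }
  rbind(
    mk("c1", "A", "High", "laboratory", "constant", 40, 0.50),
    mk("c1", "A", "High", "laboratory", "drying",   32, 0.40),
    mk("c2", "B", "High", "mesocosm",   "constant", 55, 0.80),
    mk("c2", "B", "High", "mesocosm",   "drying",   45, 0.70),
    mk("c3", "C", "Low",  "laboratory", "constant", 80, 1.20),
    mk("c3", "C", "Low",  "laboratory", "drying",   78, 1.15),
    mk("c4", "D", "Low",  "field",      "constant", 95, 1.50)
  )
}

tiny_tree <- function() {
  grafen_branch_lengths(parse_newick("((A,B),(C,D));"))
}

# assign High/Low by thresholding an independent BM draw; guarantees both
# groups are represented
clustered_groups <- function(tree) {
  x <- simulate_bm_traits(tree, sigma2 = 1)
  g <- ifelse(x > stats::median(x), "High", "Low")
  if (min(table(factor(g, c("Low", "High")))) < 2) {
    g[order(x)[1:2]] <- "Low"
    g[order(x, decreasing = TRUE)[1:2]] <- "High"
  }
  g
}
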