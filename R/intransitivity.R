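# Intransitivity metrics: exclusion digraph, competitive ranks, low-rank
# exclusions (LRE) and rock-paper-scissors (RPS) triplets with their null
# expectations.
#
# Exclusion defines a tournament-like digraph on the community: for each
# excluding pair the winner points at the loser.  A hierarchy gives a
# transitive tournament (no cycles, no upsets); intransitivity shows up as
# RPS 3-cycles and as exclusions where the lower-ranked species beats the
# higher-ranked one.

#' Build the exclusion digraph of a community
#'
#' For pairs with exactly one exclusionary coefficient, the edge points from
#' the non-excluded species to the excluded one (`j -> i` when
#' `A*[i,j] < -1 <= A*[j,i]`: j harms i beyond self-regulation).  Pairs with
#' both coefficients below -1 (bistable pairs) are oriented per
#' `direction_rule`: `"stronger_effect"` (default) lets the species hit by
#' the larger-magnitude coefficient lose (ties: the lower index wins,
#' deterministically); `"unoriented"` leaves them without an edge, excluded
#' from rank/LRE but still counted as excluding pairs for triplet
#' membership.
#'
#' @param community a `glv_community` (or bare square matrix, treated as
#'   `A*`).
#' @param direction_rule `"stronger_effect"` or `"unoriented"`.
#' @return object of class `glv_exclusion_graph`: list with `nodes`
#'   (local indices `1..S*`), `pool_indices`, `edges` (two-column matrix
#'   winner, loser), `bistable_pairs`, `direction_rule`,
#'   `n_excluding_pairs`.
#' @export
exclusion_digraph <- function(community,
                              direction_rule = c("stronger_effect",
                                                 "unoriented")) {
  direction_rule <- match.arg(direction_rule)
  A <- if (inherits(community, "glv_community")) community$A_star
       else community
  check_square_matrix(A, "A_star")
  S <- nrow(A)
  pool_idx <- if (inherits(community, "glv_community"))
    community$pool_indices else seq_len(S)
  edges <- matrix(integer(0), 0, 2,
                  dimnames = list(NULL, c("winner", "loser")))
  bistable <- matrix(integer(0), 0, 2)
  if (S >= 2) {
    for (i in seq_len(S - 1)) {
      for (j in seq((i + 1), S)) {
        eij <- A[i, j] < -1   # j excludes i
        eji <- A[j, i] < -1   # i excludes j
        if (eij && eji) {
          bistable <- rbind(bistable, c(i, j))
          if (direction_rule == "stronger_effect") {
            loser <- if (abs(A[i, j]) >= abs(A[j, i])) i else j
            winner <- if (loser == i) j else i
            edges <- rbind(edges, c(winner, loser))
          }
        } else if (eij) {
          edges <- rbind(edges, c(j, i))
        } else if (eji) {
          edges <- rbind(edges, c(i, j))
        }
      }
    }
  }
  n_unoriented <- if (direction_rule == "unoriented") nrow(bistable) else 0L
  structure(list(
    nodes = seq_len(S), pool_indices = pool_idx,
    edges = edges, bistable_pairs = bistable,
    direction_rule = direction_rule,
    n_excluding_pairs = nrow(edges) + n_unoriented
  ), class = "glv_exclusion_graph")
}

#' @export
print.glv_exclusion_graph <- function(x, ...) {
  cat(sprintf(
    "Exclusion digraph: %d species, %d excluding pairs (%d bistable, rule %s)\n",
    length(x$nodes), x$n_excluding_pairs, nrow(x$bistable_pairs),
    x$direction_rule))
  invisible(x)
}

#' Competitive ranks and low-rank-exclusion fraction
#'
#' The rank of each species is (wins - losses) / (S* - 1), wins and losses
#' counted over the oriented exclusion edges.  A low-rank exclusion (LRE)
#' is an edge whose winner has strictly lower rank than its loser (ties are
#' not upsets).  Because LRE motifs require several exclusions, the
#' corrected fraction is reported only for communities with at least four
#' excluding pairs (`NA` otherwise); the raw fraction is always reported.
#'
#' @param graph a `glv_exclusion_graph`.
#' @return list with `ranks`, `lre_fraction_raw`, `lre_fraction_corrected`,
#'   `n_exclusions`.
#' @export
ranks_and_lre <- function(graph) {
  if (!inherits(graph, "glv_exclusion_graph"))
    glv_error("`graph` must come from exclusion_digraph()",
              "glv_input_error")
  S <- length(graph$nodes)
  wins <- tabulate(graph$edges[, 1], S)
  losses <- tabulate(graph$edges[, 2], S)
  ranks <- if (S > 1) (wins - losses) / (S - 1) else numeric(S)
  ne <- nrow(graph$edges)
  lre_raw <- if (ne > 0)
    mean(ranks[graph$edges[, 1]] < ranks[graph$edges[, 2]]) else NA_real_
  lre_corr <- if (graph$n_excluding_pairs >= 4) lre_raw else NA_real_
  list(ranks = ranks, lre_fraction_raw = lre_raw,
       lre_fraction_corrected = lre_corr,
       n_exclusions = graph$n_excluding_pairs)
}

#' Rock-paper-scissors fraction of fully excluding triplets
#'
#' A triplet is a trio of species whose three pairs are all excluding; it is
#' RPS when its oriented edges form a directed 3-cycle.  Of the 8 equally
#' likely orientations of a triplet, exactly 2 are cyclic, so the null
#' expectation of the RPS fraction is 0.25.  Triplets containing an
#' unoriented bistable pair count in the denominator but cannot be scored
#' as cyclic.
#'
#' @param community a `glv_community` (or bare `A*` matrix).
#' @param graph optional pre-built `glv_exclusion_graph` (rebuilt from the
#'   community when omitted).
#' @return list with `rps_fraction` (`NA` when no triplet exists),
#'   `n_rps`, `n_triplets`, `null_rps = 0.25`.
#' @export
rps_fraction <- function(community, graph = NULL) {
  A <- if (inherits(community, "glv_community")) community$A_star
       else community
  check_square_matrix(A, "A_star")
  if (is.null(graph)) graph <- exclusion_digraph(community)
  S <- nrow(A)
  excl <- pmin(A, t(A)) < -1          # pair is excluding
  beats <- matrix(FALSE, S, S)
  if (nrow(graph$edges))
    beats[graph$edges] <- TRUE        # winner row, loser column
  n_trip <- 0L
  n_rps <- 0L
  if (S >= 3) {
    trios <- utils::combn(S, 3)
    for (t in seq_len(ncol(trios))) {
      i <- trios[1, t]; j <- trios[2, t]; k <- trios[3, t]
      if (!(excl[i, j] && excl[i, k] && excl[j, k])) next
      n_trip <- n_trip + 1L
      sub <- beats[c(i, j, k), c(i, j, k)]
      # cyclic iff every species wins exactly once within the trio
      if (sum(sub) == 3 && all(rowSums(sub) == 1)) n_rps <- n_rps + 1L
    }
  }
  list(rps_fraction = if (n_trip > 0) n_rps / n_trip else NA_real_,
       n_rps = n_rps, n_triplets = n_trip, null_rps = 0.25)
}

#' Full intransitivity report for a community
#'
#' Combines [ranks_and_lre()] and [rps_fraction()] under one direction
#' rule.
#'
#' @inheritParams exclusion_digraph
#' @return object of class `glv_intransitivity_report`.
#' @export
intransitivity_report <- function(community,
                                  direction_rule = "stronger_effect") {
  graph <- exclusion_digraph(community, direction_rule)
  rl <- ranks_and_lre(graph)
  rp <- rps_fraction(community, graph)
  structure(c(rl, rp, list(direction_rule = direction_rule)),
            class = "glv_intransitivity_report")
}

#' @export
print.glv_intransitivity_report <- function(x, ...) {
  cat(sprintf(
    "Intransitivity report: %d exclusions, LRE(raw) = %.3f, RPS = %.3f (%d/%d triplets, null 0.25)\n",
    x$n_exclusions, x$lre_fraction_raw, x$rps_fraction, x$n_rps,
    x$n_triplets))
  invisible(x)
}

# permute the off-diagonal elements of A, keeping the zero diagonal
reshuffle_offdiag <- function(A) {
  off <- row(A) != col(A)
  A[off] <- sample(A[off])
  A
}

#' Intransitivity scan across interaction structures
#'
#' Samples stable EC communities per structure and community size, computes
#' the mean and sd of corrected LRE and RPS fractions, and returns a summary
#' table.  The `"reshuffled"` control permutes the off-diagonal elements of
#' each EC community found under `"random"` interactions, erasing structure
#' while keeping the coefficient distribution.  Deterministic given `seed`.
#'
#' @param structures subset of
#'   `{"random", "reshuffled", "triangular", "k_correlated", "crossfeeding"}`.
#' @param sizes community sizes `S*` to sample.
#' @param n_communities EC communities requested per structure and size.
#' @param mu,sigma,S pool parameters for the Gaussian families.
#' @param n_pools pools drawn per structure/size (fresh matrix each).
#' @param n_samples subset draws per pool and size.
#' @param direction_rule forwarded to [exclusion_digraph()].
#' @param seed master RNG seed.
#' @return data.frame with columns `structure, S_star, n_communities,
#'   mean_lre, sd_lre, mean_rps, sd_rps, n_with_4plus_exclusions`.
#' @export
intransitivity_scan <- function(structures = c("random", "reshuffled"),
                                sizes = 4:8, n_communities = 50,
                                mu = -1, sigma = 0.5, S = 40,
                                n_pools = 20, n_samples = 2000,
                                direction_rule = "stronger_effect",
                                seed = NULL) {
  valid <- c("random", "reshuffled", "triangular", "k_correlated",
             "crossfeeding")
  if (!all(structures %in% valid))
    glv_error("unknown structure in `structures`", "glv_config_error")
  if (n_communities < 1)
    glv_error("`n_communities` must be >= 1", "glv_config_error")

  need_random <- any(c("random", "reshuffled") %in% structures)
  base_structs <- setdiff(structures, "reshuffled")
  if (need_random) base_structs <- union(base_structs, "random")

  # collect EC communities (A* matrices) per structure and size
  found <- list()
  for (st in base_structs) {
    spec <- ensemble_spec(S = S, mu = mu, sigma = sigma, structure = st,
                          seed = NULL)
    for (sz in sizes) {
      key <- paste(st, sz)
      mats <- list()
      for (p in seq_len(n_pools)) {
        if (length(mats) >= n_communities) break
        pool <- sample_matrix(spec,
                              seed = spawn_seed(seed, 7919L * p + 131L * sz +
                                                  match(st, valid)))
        cms <- sample_stable_subsets(pool, sz, n_samples,
                                     seed = spawn_seed(seed,
                                                       104729L * p + sz))
        for (cm in cms) {
          if (count_excluding_pairs(cm$A_star) >= 1)
            mats[[length(mats) + 1L]] <- cm$A_star
          if (length(mats) >= n_communities) break
        }
      }
      found[[key]] <- mats
    }
  }

  summarize <- function(structure, sz, mats) {
    lre <- rps <- numeric(0)
    n4 <- 0L
    for (A in mats) {
      g <- exclusion_digraph(A, direction_rule)
      rl <- ranks_and_lre(g)
      rp <- rps_fraction(A, g)
      if (!is.na(rl$lre_fraction_corrected)) {
        lre <- c(lre, rl$lre_fraction_corrected)
        n4 <- n4 + 1L
      }
      if (!is.na(rp$rps_fraction)) rps <- c(rps, rp$rps_fraction)
    }
    data.frame(structure = structure, S_star = sz,
               n_communities = length(mats),
               mean_lre = if (length(lre)) mean(lre) else NA_real_,
               sd_lre = if (length(lre) > 1) stats::sd(lre) else NA_real_,
               mean_rps = if (length(rps)) mean(rps) else NA_real_,
               sd_rps = if (length(rps) > 1) stats::sd(rps) else NA_real_,
               n_with_4plus_exclusions = n4)
  }

  rows <- list()
  for (st in structures) {
    for (sz in sizes) {
      mats <- if (st == "reshuffled") {
        with_seed(spawn_seed(seed, 999983L + sz),
                  lapply(found[[paste("random", sz)]], reshuffle_offdiag))
      } else {
        found[[paste(st, sz)]]
      }
      rows[[length(rows) + 1L]] <- summarize(st, sz, mats)
    }
  }
  do.call(rbind, rows)
}
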