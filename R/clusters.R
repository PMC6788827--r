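# Cluster-based permutation inference on paired differences.
#
# Shared core for the 1-D (time) and 2-D (train x test matrix) tests:
# element-wise paired t values, supra-threshold clusters (opposite signs
# kept separate), cluster mass = sum of |t|, and a max-mass null built by
# flipping the sign of each subject's difference (full enumeration of the
# 2^S flips when 2^S <= 4096, Monte-Carlo otherwise).

# t values for one sign pattern applied to the difference matrix D (S x P).
# ss = colSums(D^2) is invariant under sign flips, which makes the
# enumeration a single matrix product.
tFromSums <- function(sums, ss, S) {
  m <- sums / S
  v <- (ss - S * m^2) / (S - 1)
  v[v < 0] <- 0
  se <- sqrt(v / S)
  t <- m / se
  t[se == 0 & m == 0] <- 0
  t[se == 0 & m != 0] <- sign(m[se == 0 & m != 0]) * Inf
  t
}

# Label connected components of a logical vector (column-major over dims).
# connectivity "1d": adjacency along the vector; "2d": 8-neighbour
# adjacency on the dims[1] x dims[2] grid.
labelComponents <- function(mask, dims, connectivity) {
  labels <- integer(length(mask))
  if (!any(mask)) return(labels)
  if (connectivity == "1d") {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    id <- 0L
    for (k in seq_along(r$values)) {
      if (r$values[k]) {
        id <- id + 1L
        labels[starts[k]:ends[k]] <- id
      }
    }
    return(labels)
  }
  A <- dims[1]; B <- dims[2]
  m <- matrix(mask, A, B)
  lab <- matrix(0L, A, B)
  id <- 0L
  todo <- which(m)
  for (p in todo) {
    if (lab[p] != 0L) next
    id <- id + 1L
    stack <- p
    lab[p] <- id
    while (length(stack)) {
      q <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r0 <- (q - 1L) %% A + 1L
      c0 <- (q - 1L) %/% A + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        r1 <- r0 + dr; c1 <- c0 + dc
        if (r1 >= 1L && r1 <= A && c1 >= 1L && c1 <= B &&
            m[r1, c1] && lab[r1, c1] == 0L) {
          lab[r1, c1] <- id
          stack <- c(stack, (c1 - 1L) * A + r1)
        }
      }
    }
  }
  as.integer(lab)
}

# Max cluster mass (over both signs) for a t-value vector.
maxClusterMass <- function(t, tcrit, dims, connectivity) {
  best <- 0
  for (s in c(1, -1)) {
    mask <- if (s > 0) t > tcrit else t < -tcrit
    if (!any(mask)) next
    lab <- labelComponents(mask, dims, connectivity)
    masses <- tapply(abs(t)[lab > 0], lab[lab > 0], sum)
    best <- max(best, masses)
  }
  best
}

# Core test. D: subjects x elements matrix of paired differences.
clusterMassCore <- function(D, dims, connectivity, element_p, n_perm, seed) {
  S <- nrow(D)
  stopIfNot(S >= 6, "cluster permutation test requires at least 6 subjects")
  if (n_perm < 100) warning("fewer than 100 permutations: p values are unstable")
  df <- S - 1
  tcrit <- stats::qt(1 - element_p / 2, df)
  ss <- colSums(D^2)
  t_obs <- tFromSums(colSums(D), ss, S)

  # observed clusters, positive and negative kept separate
  rows <- list(); members <- list(); id <- 0L
  for (sgn in c(1, -1)) {
    mask <- if (sgn > 0) t_obs > tcrit else t_obs < -tcrit
    lab <- labelComponents(mask, dims, connectivity)
    if (!any(lab > 0)) next
    for (k in seq_len(max(lab))) {
      idx <- which(lab == k)
      id <- id + 1L
      rows[[id]] <- data.frame(id = id, sign = sgn, n_elements = length(idx),
                               mass = sum(abs(t_obs[idx])), p_value = NA_real_)
      members[[id]] <- idx
    }
  }

  # max-mass null over sign-flip patterns
  exhaustive <- 2^S <= 4096
  if (exhaustive) {
    Q <- as.integer(2^S)
    signs <- matrix(1, Q, S)
    for (j in seq_len(S)) {
      signs[, j] <- ifelse(bitwAnd(seq_len(Q) - 1L, bitwShiftL(1L, j - 1L)) > 0, -1, 1)
    }
  } else {
    Q <- as.integer(n_perm)
    signs <- withSeed(seed, matrix(sample(c(-1, 1), Q * S, replace = TRUE), Q, S))
  }
  null_max <- numeric(Q)
  chunk <- 512L
  for (a in seq(1L, Q, by = chunk)) {
    b <- min(a + chunk - 1L, Q)
    SS <- matrix(ss, b - a + 1L, length(ss), byrow = TRUE)
    # tFromSums is elementwise, so matrix-shaped sums work directly
    Tq <- tFromSums(signs[a:b, , drop = FALSE] %*% D, SS, S)
    for (q in seq_len(b - a + 1L)) {
      null_max[a + q - 1L] <- maxClusterMass(Tq[q, ], tcrit, dims, connectivity)
    }
  }

  clusters <- if (id > 0) do.call(rbind, rows) else
    data.frame(id = integer(0), sign = integer(0), n_elements = integer(0),
               mass = numeric(0), p_value = numeric(0))
  if (id > 0) {
    for (k in seq_len(id)) {
      if (exhaustive) {
        clusters$p_value[k] <- mean(null_max >= clusters$mass[k])
      } else {
        clusters$p_value[k] <- (1 + sum(null_max >= clusters$mass[k])) / (Q + 1)
      }
    }
    # never report below the resolution of the null
    clusters$p_value <- pmax(clusters$p_value, 1 / (Q + 1))
  }
  new("ClusterSet", clusters = clusters, members = members,
      tmap = matrix(t_obs, dims[1], dims[2]),
      elementThresholdP = element_p, nPermutations = Q,
      connectivity = if (connectivity == "1d") "1d-adjacent" else "2d-8neighbor")
}

#' Within-subject 1-D cluster-based permutation test
#'
#' Paired two-tailed t test at each time sample between two per-subject
#' waveforms; temporally adjacent supra-threshold samples (element-level
#' p < `element_p`) form clusters, scored by the sum of |t|, and compared
#' against a max-mass null obtained by flipping condition labels within
#' subjects. With up to 12 subjects all 2^S flips are enumerated;
#' otherwise `n_perm` random flips are drawn.
#'
#' @param cond_a,cond_b Subjects x time matrices of condition waveforms.
#'   `cond_b` may be a scalar (e.g. 0) for a one-sample test against a
#'   constant, as used for group-level tests on regression t values.
#' @param element_p Element-forming threshold (default 0.05).
#' @param n_perm Monte-Carlo permutations when enumeration is infeasible.
#' @param seed Seed for Monte-Carlo flips.
#' @return A [ClusterSet-class].
#' @export
clusterPermutation1D <- function(cond_a, cond_b = 0, element_p = 0.05,
                                 n_perm = 1000, seed = NULL) {
  cond_a <- as.matrix(cond_a)
  if (length(cond_b) == 1) {
    cond_b <- matrix(cond_b, nrow(cond_a), ncol(cond_a))
  }
  stopIfNot(all(dim(cond_a) == dim(cond_b)), "condition matrices must match")
  D <- cond_a - cond_b
  clusterMassCore(D, dims = c(1L, ncol(D)), connectivity = "1d",
                  element_p = element_p, n_perm = n_perm, seed = seed)
}

#' 2-D cluster-based permutation test on decoding matrices
#'
#' Compares true against null (shuffled-label) temporal-generalization
#' matrices across subjects: per pixel, a paired two-tailed t test; pixels
#' passing the element-level threshold (default p < 0.01) are clustered
#' under 8-connectivity (cardinal or diagonal neighbours); cluster mass is
#' the sum of |t|, tested against a max-mass sign-flip null.
#'
#' @param true,null Subjects x train x test 3-D arrays (or lists of
#'   per-subject matrices) of Az values.
#' @param element_p Element-forming threshold (default 0.01).
#' @param n_perm Monte-Carlo permutations when enumeration is infeasible.
#' @param seed Seed for Monte-Carlo flips.
#' @return A [ClusterSet-class].
#' @export
clusterPermutation2D <- function(true, null, element_p = 0.01,
                                 n_perm = 1000, seed = NULL) {
  to3d <- function(x) {
    if (is.list(x)) {
      x <- simplify2array(x)        # train x test x subjects
      x <- aperm(x, c(3, 1, 2))
    }
    x
  }
  true <- to3d(true); null <- to3d(null)
  stopIfNot(length(dim(true)) == 3 && all(dim(true) == dim(null)),
            "true and null must be matching subjects x train x test arrays")
  S <- dim(true)[1]; A <- dim(true)[2]; B <- dim(true)[3]
  D <- matrix(true - null, S, A * B)
  clusterMassCore(D, dims = c(A, B), connectivity = "2d",
                  element_p = element_p, n_perm = n_perm, seed = seed)
}
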