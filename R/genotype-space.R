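# Genotype universe and Mendelian inheritance kernels.
#
# A genotype is a vector of length k over {0, 1, 2}: the number of mutant
# alleles at each of k unlinked loci. Genotypes are indexed by a base-3
# code with locus 1 least significant, so code(g) = sum_j g_j * 3^(j-1)
# and compartment vectors are addressed as code + 1.

#' Enumerate all genotypes for k loci
#'
#' Diploid genotypes over `k` unlinked biallelic loci are represented as
#' vectors over \{0, 1, 2\} (mutant-allele counts per locus). There are
#' `3^k` such genotypes, returned in base-3 code order with locus 1 as
#' the least-significant digit.
#'
#' @param k Number of loci (1--8).
#' @return Integer matrix with `3^k` rows and `k` columns; row `i` is the
#'   genotype with code `i - 1`.
#' @examples
#' enumerate_genotypes(2)
#' @export
enumerate_genotypes <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k != as.integer(k) ||
      k < 1L || k > 8L) {
    stop("`k` must be a single integer between 1 and 8", call. = FALSE)
  }
  k <- as.integer(k)
  g <- as.matrix(expand.grid(rep(list(0:2), k), KEEP.OUT.ATTRS = FALSE))
  dimnames(g) <- list(NULL, paste0("locus", seq_len(k)))
  storage.mode(g) <- "integer"
  g
}

#' Convert genotype vectors to base-3 codes and back
#'
#' @param g Genotype vector (length k) or matrix (rows are genotypes).
#' @param code Integer code(s) in `[0, 3^k)`.
#' @param k Number of loci.
#' @return `genotype_code()` returns integer code(s); `code_to_genotype()`
#'   returns a genotype matrix with one row per code.
#' @export
genotype_code <- function(g) {
  if (is.null(dim(g))) g <- matrix(g, nrow = 1L)
  stopifnot(all(g %in% 0:2))
  as.integer(g %*% 3^(seq_len(ncol(g)) - 1L))
}

#' @rdname genotype_code
#' @export
code_to_genotype <- function(code, k) {
  stopifnot(all(code >= 0L), all(code < 3^k))
  g <- matrix(0L, nrow = length(code), ncol = k)
  rest <- as.integer(code)
  for (j in seq_len(k)) {
    g[, j] <- rest %% 3L
    rest <- rest %/% 3L
  }
  colnames(g) <- paste0("locus", seq_len(k))
  g
}

#' Phenotype of a genotype under a dominance vector
#'
#' Element `j` of the phenotype is 1 when the mutant effect at locus `j`
#' is expressed: always for mutant homozygotes (`g_j = 2`), and for
#' heterozygotes only when the mutant allele is dominant (`d_j = 1`).
#'
#' @param g Genotype vector or matrix (rows are genotypes).
#' @param d Dominance vector of length k with entries in \{0, 1\}.
#' @return 0/1 phenotype vector (or matrix matching `g`).
#' @export
phenotype_of <- function(g, d) {
  vec <- is.null(dim(g))
  if (vec) g <- matrix(g, nrow = 1L)
  if (length(d) != ncol(g)) {
    stop("dominance vector length must equal the number of loci", call. = FALSE)
  }
  if (!all(d %in% 0:1)) stop("dominance entries must be 0 or 1", call. = FALSE)
  dm <- matrix(d, nrow = nrow(g), ncol = ncol(g), byrow = TRUE)
  p <- (g == 2L) | (g >= 1L & dm == 1L)
  p <- p * 1L
  if (vec) p <- as.integer(p[1L, ])
  p
}

#' Per-locus Mendelian inheritance kernels
#'
#' `selfing_kernel()` gives the offspring allele-count distribution at one
#' locus when a parent with the given state self-fertilizes; each gamete
#' carries the mutant allele with probability `state / 2`, independently.
#' `crossing_kernel()` does the same for a hermaphrodite x male pair.
#'
#' @param parent,herm,male Locus state(s) in \{0, 1, 2\}.
#' @return Numeric vector of length 3: probabilities of offspring state
#'   0, 1, 2 at that locus.
#' @examples
#' selfing_kernel(1)        # 1/4, 1/2, 1/4
#' crossing_kernel(2, 0)    # all heterozygous
#' @export
selfing_kernel <- function(parent) {
  crossing_kernel(parent, parent)
}

#' @rdname selfing_kernel
#' @export
crossing_kernel <- function(herm, male) {
  stopifnot(length(herm) == 1L, length(male) == 1L,
            herm %in% 0:2, male %in% 0:2)
  ph <- herm / 2
  pm <- male / 2
  c(
    (1 - ph) * (1 - pm),
    ph * (1 - pm) + (1 - ph) * pm,
    ph * pm
  )
}

# 3x3 matrix T[parent_state + 1, offspring_state + 1] for selfing.
.selfing_matrix <- function() {
  t(vapply(0:2, selfing_kernel, numeric(3)))
}

# 3x2 gamete matrix G[state + 1, allele + 1]: probability a parent in the
# given locus state transmits a wild-type (0) or mutant (1) allele.
.gamete_matrix <- function() {
  rbind(c(1, 0), c(0.5, 0.5), c(0, 1))
}

#' Offspring genotype distribution for one parent (selfing) or pair
#'
#' Loci are unlinked, so the joint offspring distribution is the product
#' over loci of the per-locus kernels.
#'
#' @param parent_a Genotype vector of the (selfing) parent or hermaphrodite.
#' @param parent_b Genotype vector of the male (crossing mode only).
#' @param mode `"selfing"` or `"crossing"`.
#' @return Numeric vector of length `3^k` over genotype codes; sums to 1.
#' @export
offspring_distribution <- function(parent_a, parent_b = NULL,
                                   mode = c("selfing", "crossing")) {
  mode <- match.arg(mode)
  if (mode == "crossing" && is.null(parent_b)) {
    stop("crossing mode requires a second parent", call. = FALSE)
  }
  if (mode == "selfing") parent_b <- parent_a
  stopifnot(length(parent_a) == length(parent_b))
  k <- length(parent_a)
  out <- 1
  for (j in rev(seq_len(k))) {
    out <- outer(crossing_kernel(parent_a[j], parent_b[j]), out)
  }
  # axis j of the nested outer product is locus j, so the linear order is
  # exactly base-3 code order (locus 1 fastest)
  as.vector(out)
}

#' Single-step mutational neighbours of a genotype
#'
#' Neighbours differ at exactly one locus by one allele: 0 -> 1, 1 -> 0,
#' 1 -> 2, or 2 -> 1. A genotype has `#\{g_j = 0\} + #\{g_j = 2\} +
#' 2 #\{g_j = 1\}` neighbours.
#'
#' @param g Genotype vector.
#' @return Integer matrix of neighbour genotypes, one per row.
#' @export
mutation_neighbors <- function(g) {
  k <- length(g)
  out <- list()
  for (j in seq_len(k)) {
    for (delta in c(-1L, 1L)) {
      s <- g[j] + delta
      if (s >= 0L && s <= 2L) {
        nb <- g
        nb[j] <- s
        out[[length(out) + 1L]] <- nb
      }
    }
  }
  m <- do.call(rbind, out)
  storage.mode(m) <- "integer"
  colnames(m) <- paste0("locus", seq_len(k))
  m
}

# ---- cached per-k machinery -------------------------------------------------

.androsim_cache <- new.env(parent = emptyenv())

# Precomputed tables for a given locus count:
#   genotypes : 3^k x k matrix
#   selfing_m : 3x3 per-locus selfing transition
#   gamete_m  : 3x2 per-locus gamete transition
#   combine   : (2^k)^2 -> 3^k index map, gamete pair to offspring code + 1
#   neighbors : list over genotype code + 1 of neighbour indices (code + 1)
.k_tables <- function(k) {
  key <- paste0("k", k)
  tab <- .androsim_cache[[key]]
  if (!is.null(tab)) return(tab)
  genotypes <- enumerate_genotypes(k)
  gam <- as.matrix(expand.grid(rep(list(0:1), k), KEEP.OUT.ATTRS = FALSE))
  # offspring code for gamete pair (a, b): digits a_j + b_j
  pow3 <- 3^(seq_len(k) - 1L)
  na <- nrow(gam)
  idx <- matrix(0L, na, na)
  acode <- gam %*% pow3
  for (i in seq_len(na)) {
    idx[, i] <- as.integer(acode + acode[i]) + 1L
  }
  neighbors <- lapply(seq_len(nrow(genotypes)), function(i) {
    genotype_code(mutation_neighbors(genotypes[i, ])) + 1L
  })
  tab <- list(
    k = k,
    genotypes = genotypes,
    selfing_m = .selfing_matrix(),
    gamete_m = .gamete_matrix(),
    combine_idx = idx,
    neighbors = neighbors
  )
  .androsim_cache[[key]] <- tab
  tab
}

# Contract a weight vector over genotype codes (length 3^k) with a
# per-locus d_out x 3 matrix applied at every locus. Used for the selfing
# step (3 -> 3 offspring states) and for gamete distributions (3 -> 2
# transmitted alleles). Axis j of the array corresponds to locus j.
.tensor_contract <- function(x, m, k) {
  d_in <- ncol(m)
  d_out <- nrow(m)
  dims <- rep(d_in, k)
  for (j in seq_len(k)) {
    perm <- c(j, setdiff(seq_len(k), j))
    xa <- aperm(array(x, dims), perm)
    y <- m %*% matrix(xa, nrow = dims[j])
    x <- aperm(array(y, c(d_out, dims[perm][-1L])), order(perm))
    dims[j] <- d_out
  }
  as.vector(x)
}

# Weighted gamete distribution over 2^k gamete haplotypes produced by a
# population weighted by w over genotype codes. t(gamete_m) is 2x3.
.gamete_distribution <- function(w, tab) {
  .tensor_contract(w, t(tab$gamete_m), tab$k)
}

# Expected offspring genotype distribution of a selfing population
# weighted by w (not normalized; output totals sum(w)).
.selfing_offspring <- function(w, tab) {
  .tensor_contract(w, t(tab$selfing_m), tab$k)
}

# Combine a hermaphrodite gamete distribution and a male gamete
# distribution into an offspring genotype distribution.
.combine_gametes <- function(hg, mg, tab) {
  op <- as.vector(outer(hg, mg))
  out <- numeric(3^tab$k)
  agg <- rowsum(op, group = as.vector(tab$combine_idx))
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}
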