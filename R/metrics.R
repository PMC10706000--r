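# Evaluation suite for generated molecule sets: validity / uniqueness /
# novelty, internal diversity over Morgan-fingerprint Tanimoto similarity,
# Frechet distance between Gaussian fits of molecular features, KL-divergence
# score over physicochemical descriptors, and the SD/MAD condition-deviation
# statistics for property-conditioned sampling.

KL_DESCRIPTORS <- c("BertzCT", "MolWt", "MolLogP", "TPSA", "NumHAcceptors",
                    "NumHDonors", "NumRotatableBonds", "NumAromaticRings",
                    "NumAliphaticRings")
KL_DISCRETE <- c("NumHAcceptors", "NumHDonors", "NumRotatableBonds",
                 "NumAromaticRings", "NumAliphaticRings")

#' Validity / uniqueness / novelty report
#'
#' Validity is the fraction of generated strings that parse; uniqueness the
#' fraction of distinct canonical SMILES among the valid ones; novelty the
#' fraction of those distinct molecules absent from the training set. A zero
#' denominator yields 0 with `degenerate = TRUE`.
#'
#' @param generated character vector of generated SMILES (possibly invalid).
#' @param training_canonical character vector of canonical training SMILES.
#' @return a `generation_report`: list with fractions `valid`, `unique`,
#'   `novelty`, counts `n_total`, `n_valid`, `n_unique`, `n_novel`, and
#'   `degenerate`.
#' @export
vun_report <- function(generated, training_canonical) {
  n_total <- length(generated)
  ok <- is_valid_smiles(generated)
  valid_smiles <- if (any(ok)) canonicalize(generated[ok]) else character(0)
  n_valid <- length(valid_smiles)
  distinct <- unique(valid_smiles)
  n_unique <- length(distinct)
  novel <- setdiff(distinct, training_canonical)
  n_novel <- length(novel)
  degenerate <- n_total == 0 || n_valid == 0 || n_unique == 0
  structure(list(
    valid = if (n_total > 0) n_valid / n_total else 0,
    unique = if (n_valid > 0) n_unique / n_valid else 0,
    novelty = if (n_unique > 0) n_novel / n_unique else 0,
    n_total = n_total, n_valid = n_valid, n_unique = n_unique,
    n_novel = n_novel, degenerate = degenerate
  ), class = "generation_report")
}

#' Morgan fingerprint matrix
#'
#' @param smiles character vector of valid SMILES.
#' @param radius Morgan radius (default 2).
#' @param nbits fingerprint length (default 2048).
#' @return n x nbits binary matrix.
#' @export
morgan_matrix <- function(smiles, radius = 2L, nbits = 2048L) {
  bits <- bridge_morgan(smiles, radius, nbits)
  bad <- vapply(bits, is.null, logical(1))
  if (any(bad)) {
    stop("invalid SMILES in fingerprint input: ",
         paste(sQuote(smiles[bad]), collapse = ", "))
  }
  m <- matrix(0L, length(smiles), nbits)
  for (i in seq_along(bits)) {
    on <- unlist(bits[[i]])
    if (length(on) > 0) m[i, on + 1L] <- 1L
  }
  m
}

#' Pairwise Tanimoto similarity
#' @param fp binary fingerprint matrix (rows = molecules).
#' @return n x n similarity matrix; pairs of all-zero fingerprints get 0.
#' @export
tanimoto_matrix <- function(fp) {
  inter <- tcrossprod(fp)
  pop <- rowSums(fp)
  uni <- outer(pop, pop, "+") - inter
  t <- inter / uni
  t[uni == 0] <- 0
  t
}

#' Internal diversity of a molecule set
#'
#' `1 - (1/|S|^2) * sum over all ordered pairs (self-pairs included) of
#' T(s1, s2)^p`, with T the Tanimoto similarity of Morgan fingerprints
#' (radius 2, 2048 bits).
#'
#' @param smiles valid SMILES (invalid entries must be excluded upstream).
#' @param p exponent, 1 or 2.
#' @return diversity in \[0, 1\]; 0 when all molecules are identical.
#' @export
intdiv <- function(smiles, p = 1) {
  stopifnot(p %in% c(1, 2))
  if (length(smiles) == 0) stop("intdiv of an empty molecule set")
  t <- tanimoto_matrix(morgan_matrix(smiles))
  1 - mean(t^p)
}

#' Gaussian fit of a feature matrix
#' @param features n x d numeric matrix (one row per molecule).
#' @return a `distribution_stats`: list with `mean`, `cov`, `dim`.
#' @export
distribution_stats <- function(features) {
  stopifnot(is.matrix(features), nrow(features) >= 2)
  structure(list(mean = colMeans(features), cov = stats::cov(features),
                 dim = ncol(features)),
            class = "distribution_stats")
}

# symmetric PSD square root via eigendecomposition; tiny negative
# eigenvalues from round-off are clipped to zero
sym_sqrt <- function(m, tol = 1e-8) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  vals <- e$values
  if (any(vals < -tol * max(abs(vals), 1))) {
    stop("covariance matrix is not positive semi-definite")
  }
  vals <- pmax(vals, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

#' Frechet distance between two Gaussian fits
#'
#' `||mu_G - mu_D||^2 + Tr(Sigma_G + Sigma_D - 2 (Sigma_G Sigma_D)^{1/2})`.
#' The trace of the product square root is computed through the symmetric
#' form `sqrt(S_G)^T Sigma_D sqrt(S_G)`, which is PSD for PSD inputs; tiny
#' negative eigenvalues are clipped to zero.
#'
#' @param g,d `distribution_stats` of the generated and reference sets.
#' @return non-negative real.
#' @export
frechet_distance <- function(g, d) {
  stopifnot(inherits(g, "distribution_stats"),
            inherits(d, "distribution_stats"), g$dim == d$dim)
  sg <- sym_sqrt(g$cov)
  inner <- sym_sqrt(sg %*% d$cov %*% sg)
  val <- sum((g$mean - d$mean)^2) +
    sum(diag(g$cov)) + sum(diag(d$cov)) - 2 * sum(diag(inner))
  max(val, 0)
}

#' Benchmark score transform of a Frechet distance
#'
#' `exp(-0.2 * fcd)`, mapping distance 0 to score 1.
#' @param fcd non-negative Frechet distance.
#' @return score in (0, 1].
#' @export
guacamol_score <- function(fcd) exp(-0.2 * fcd)

#' Descriptor-based Gaussian statistics of a molecule set
#'
#' The default featurizer computes the nine physicochemical descriptors of
#' [kl_score()] and standardizes them; pass the standardization statistics of
#' the reference set via `center`/`scale` so both sides share one feature
#' space. A ChemNet-style neural featurizer can be plugged in by supplying a
#' precomputed feature matrix to [distribution_stats()] instead.
#'
#' @param smiles valid SMILES.
#' @param center,scale optional standardization vectors (defaults: this set's
#'   own mean and standard deviation).
#' @return `distribution_stats` with attributes `center` and `scale`.
#' @export
descriptor_stats <- function(smiles, center = NULL, scale = NULL) {
  x <- descriptor_matrix(smiles)
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::sd)
    scale[scale == 0] <- 1
  }
  xs <- scale(x, center = center, scale = scale)
  out <- distribution_stats(unclass(xs)[, , drop = FALSE])
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' Physicochemical descriptor matrix
#' @param smiles valid SMILES.
#' @return n x 9 matrix with the descriptors of [kl_score()] as columns.
#' @export
descriptor_matrix <- function(smiles) {
  desc <- bridge_descriptors(smiles)
  bad <- vapply(desc, is.null, logical(1))
  if (any(bad)) {
    stop("invalid SMILES in descriptor input: ",
         paste(sQuote(smiles[bad]), collapse = ", "))
  }
  m <- t(vapply(desc, function(d) unlist(d[KL_DESCRIPTORS]),
                numeric(length(KL_DESCRIPTORS))))
  colnames(m) <- KL_DESCRIPTORS
  m
}

# D_KL(P || Q) = sum_i P_i log(P_i / Q_i) between two probability vectors
# (shared support, additive smoothing applied upstream)
kl_divergence_discrete <- function(p, q) {
  sum(p * log(p / q))
}

# histogram probabilities over shared bin edges; values outside the edges are
# clamped into the end bins
hist_probs <- function(x, edges, smoothing = 1e-10) {
  x <- pmin(pmax(x, edges[1]), edges[length(edges)])
  counts <- graphics::hist(x, breaks = edges, plot = FALSE)$counts
  p <- counts / sum(counts) + smoothing
  p / sum(p)
}

#' KL-divergence score between generated and reference descriptor samples
#'
#' For each descriptor, the reference-vs-generated Kullback-Leibler divergence
#' `D_KL(P, Q) = sum_i P(i) log(P(i)/Q(i))` (P = reference) is computed over a
#' shared discretization; the score aggregates them as
#' `S = (1/k) sum_i exp(-D_KL,i)`, so identical distributions score 1.
#' Continuous descriptors use 50 histogram bins with edges from the reference
#' side; integer-valued descriptors use their discrete support. Additive
#' smoothing 1e-10 keeps the divergences finite.
#'
#' @param generated,reference valid SMILES vectors (>= 2 each), or numeric
#'   matrices of per-molecule descriptor samples with matching columns.
#' @param bins histogram bins for continuous descriptors.
#' @param smoothing additive smoothing applied to the bin probabilities.
#' @return list with `score` in (0, 1] and the per-descriptor `kl` vector.
#' @export
kl_score <- function(generated, reference, bins = 50L, smoothing = 1e-10) {
  gm <- if (is.matrix(generated)) generated else descriptor_matrix(generated)
  rm_ <- if (is.matrix(reference)) reference else descriptor_matrix(reference)
  stopifnot(ncol(gm) == ncol(rm_), nrow(gm) >= 2, nrow(rm_) >= 2)
  kl <- vapply(seq_len(ncol(rm_)), function(j) {
    ref <- rm_[, j]
    gen <- gm[, j]
    name <- colnames(rm_)[j]
    discrete <- !is.null(name) && name %in% KL_DISCRETE
    if (discrete) {
      support <- seq(min(ref, gen), max(ref, gen))
      p <- tab_probs(ref, support, smoothing)
      q <- tab_probs(gen, support, smoothing)
    } else {
      edges <- seq(min(ref), max(ref), length.out = bins + 1L)
      if (edges[1] == edges[length(edges)]) {
        edges <- edges[1] + seq(-0.5, 0.5, length.out = bins + 1L)
      }
      p <- hist_probs(ref, edges, smoothing)
      q <- hist_probs(gen, edges, smoothing)
    }
    kl_divergence_discrete(p, q)
  }, numeric(1))
  names(kl) <- colnames(rm_)
  list(score = mean(exp(-kl)), kl = kl)
}

tab_probs <- function(x, support, smoothing) {
  x <- pmin(pmax(round(x), support[1]), support[length(support)])
  counts <- tabulate(match(x, support), nbins = length(support))
  p <- counts / sum(counts) + smoothing
  p / sum(p)
}

#' Condition-deviation statistics of a generated set
#'
#' For each targeted property: MAD is the mean absolute deviation of the
#' generated property values from the target, and SD the population standard
#' deviation of those values about their own mean (`sd_about_target` is also
#' reported). Invalid strings are excluded; statistics run over all valid
#' samples.
#'
#' @param generated character vector of generated SMILES.
#' @param targets named numeric vector of property targets (subset of logP,
#'   TPSA, QED, SAS).
#' @return a `condition_deviation`: per-property list with `sd`, `mad`,
#'   `sd_about_target`, `mean`, plus `n_valid`.
#' @export
condition_deviation <- function(generated, targets) {
  stopifnot(length(targets) > 0, !is.null(names(targets)),
            all(names(targets) %in% PROPERTY_NAMES))
  ok <- is_valid_smiles(generated)
  if (!any(ok)) stop("no valid molecules to evaluate against the condition")
  recs <- molecule_records(generated[ok])
  per <- lapply(names(targets), function(p) {
    vals <- recs[[p]]
    tgt <- targets[[p]]
    list(sd = sqrt(mean((vals - mean(vals))^2)),
         mad = mean(abs(vals - tgt)),
         sd_about_target = sqrt(mean((vals - tgt)^2)),
         mean = mean(vals))
  })
  names(per) <- names(targets)
  structure(c(per, list(n_valid = nrow(recs))), class = "condition_deviation")
}

#' Full evaluation report
#'
#' Convenience wrapper running the whole suite: validity/uniqueness/novelty,
#' IntDiv1/IntDiv2, descriptor-space Frechet distance (+ score transform),
#' KL score, and (when targets are given) condition deviations.
#'
#' @param generated generated SMILES (raw, unfiltered).
#' @param reference canonical training SMILES.
#' @param targets optional named property targets.
#' @return list of metric results.
#' @export
evaluate_generation <- function(generated, reference, targets = NULL) {
  rep_ <- vun_report(generated, reference)
  ok <- is_valid_smiles(generated)
  valid <- if (any(ok)) canonicalize(generated[ok]) else character(0)
  out <- list(vun = rep_)
  if (length(valid) >= 2) {
    out$intdiv1 <- intdiv(valid, 1)
    out$intdiv2 <- intdiv(valid, 2)
    ref_stats <- descriptor_stats(reference)
    gen_stats <- descriptor_stats(valid, center = attr(ref_stats, "center"),
                                  scale = attr(ref_stats, "scale"))
    out$fcd <- frechet_distance(gen_stats, ref_stats)
    out$fcd_score <- guacamol_score(out$fcd)
    out$kl <- kl_score(valid, reference)
  }
  if (!is.null(targets) && length(targets) > 0 && any(ok)) {
    out$condition <- condition_deviation(generated, targets)
  }
  out
}
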