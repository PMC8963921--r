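#' Extract muscle synergies by non-negative matrix factorization
#'
#' Factorizes a non-negative muscle-activation matrix `M` (muscles x time)
#' into spatial patterns `W` (muscles x N) and temporal patterns `C`
#' (N x time) with `M ~ W C`, using Lee-Seung multiplicative updates on the
#' Frobenius objective. Several random restarts are run from a fixed seed
#' and the best Frobenius fit is kept (ties resolved by restart order).
#' After fitting, each column of `W` is rescaled to unit maximum with the
#' inverse scaling absorbed into `C`, so spatial patterns are comparable
#' across trials and temporal amplitudes carry the activation level.
#'
#' @param M Non-negative matrix, muscles in rows (rownames = muscle labels),
#'   time/progress in columns.
#' @param N Number of synergies (default 4: lumbar flexion, hip raise, body
#'   extension, posture control phases of sit-to-stand).
#' @param seed RNG seed for the restarts.
#' @param restarts Number of random initializations (default 20).
#' @param max_iter Maximum multiplicative updates per restart (default 2000).
#' @param tol Relative Frobenius-error change for convergence (default 1e-6).
#' @return A `synergy_set`: list with `W`, `C`, `N`,
#'   `reconstruction_quality` (%), `error` (Frobenius), `restart_errors`.
#' @export
extract_synergies <- function(M, N = 4L, seed = 1L, restarts = 20L,
                              max_iter = 2000L, tol = 1e-6) {
  M <- as.matrix(M)
  if (any(M < 0)) sts_error("activation matrix must be non-negative", "sts_validation_error")
  if (N > nrow(M)) sts_error("more synergies than muscles", "sts_validation_error")
  stopifnot_finite(M, "activation matrix")

  draws <- local_runif(2L * restarts * (nrow(M) + ncol(M)) * N, seed = seed)
  per <- (nrow(M) + ncol(M)) * N
  best <- NULL
  errs <- numeric(restarts)
  for (rr in seq_len(restarts)) {
    block <- draws[((rr - 1L) * 2L * per + 1L):(rr * 2L * per)]
    W <- matrix(block[seq_len(nrow(M) * N)], nrow(M), N) * max(M) + 1e-6
    C <- matrix(block[nrow(M) * N + seq_len(ncol(M) * N)], N, ncol(M)) + 1e-6
    fit <- nnmf_mu(M, W, C, max_iter, tol)
    errs[rr] <- fit$error
    if (is.null(best) || fit$error < best$error) best <- fit  # ties keep earlier seed
  }
  W <- best$W; C <- best$C
  scl <- apply(W, 2, max)
  scl[scl == 0] <- 1
  W <- sweep(W, 2, scl, `/`)
  C <- sweep(C, 1, scl, `*`)
  rownames(W) <- rownames(M)
  structure(
    list(W = W, C = C, N = N,
         reconstruction_quality = reconstruction_quality(M, W, C),
         error = best$error, restart_errors = errs, error_trace = best$trace,
         seed = seed, restarts = restarts),
    class = "synergy_set"
  )
}

# Lee-Seung multiplicative updates for min ||M - WC||_F
nnmf_mu <- function(M, W, C, max_iter, tol) {
  eps <- .Machine$double.eps
  err_prev <- Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    C <- C * (t(W) %*% M) / (t(W) %*% W %*% C + eps)
    W <- W * (M %*% t(C)) / (W %*% (C %*% t(C)) + eps)
    if (it %% 10L == 0L || it == max_iter) {
      err <- sqrt(sum((M - W %*% C)^2))
      trace <- c(trace, err)
      if (is.finite(err_prev) && abs(err_prev - err) <= tol * max(err_prev, eps)) break
      err_prev <- err
    }
  }
  list(W = W, C = C, error = sqrt(sum((M - W %*% C)^2)), trace = trace)
}

#' Synergy reconstruction quality
#'
#' Global variance accounted for by the factorization:
#' `100 * (1 - ||M - WC||_F^2 / ||M||_F^2)`.
#'
#' @param M Activation matrix; `W`, `C` conforming factors.
#' @param W,C Spatial and temporal pattern matrices.
#' @return Percentage in `[0, 100]` (negative values possible for fits worse
#'   than the zero matrix).
#' @export
reconstruction_quality <- function(M, W, C) {
  M <- as.matrix(M)
  if (sum(M^2) == 0) sts_error("zero activation matrix: quality undefined",
                               "sts_degenerate_error")
  100 * (1 - sum((M - W %*% C)^2) / sum(M^2))
}

#' Per-synergy amplitude and timing features
#'
#' Peak level (maximum of each temporal pattern) and peak time (its location
#' on the motion-progress axis, %; first index on ties).
#'
#' @param synergies A `synergy_set` from [extract_synergies()].
#' @return Data frame with one row per synergy: `synergy`, `peak_level`,
#'   `peak_time_pct`.
#' @export
synergy_features <- function(synergies) {
  C <- synergies$C
  tmax <- ncol(C)
  idx <- apply(C, 1, which.max)
  data.frame(
    synergy = seq_len(nrow(C)),
    peak_level = apply(C, 1, max),
    peak_time_pct = 100 * (idx - 1) / (tmax - 1)
  )
}

#' Default spatial templates for synergy ordering
#'
#' Phase-labeled reference spatial patterns used to order extracted
#' synergies consistently across trials: synergy 1 (lumbar flexion,
#' RA-dominant), synergy 2 (hip raise, TA-dominant), synergy 3 (body
#' extension, VAS/ES-dominant), synergy 4 (posture control, SOL-dominant).
#'
#' @param muscles Character vector of muscle row labels.
#' @return muscles x 4 template matrix.
#' @export
synergy_reference_templates <- function(muscles = measured_muscle_names()) {
  W <- matrix(0.05, length(muscles), 4, dimnames = list(muscles, NULL))
  put <- function(syn, vals) for (nm in names(vals)) {
    if (nm %in% muscles) W[nm, syn] <<- vals[[nm]]
  }
  put(1, c(RA = 1.0, RF = 0.5, TA = 0.3))
  put(2, c(TA = 1.0, RF = 0.6, VAS = 0.4))
  put(3, c(VAS = 1.0, ES = 0.9, GMAX = 0.7, BFL = 0.4))
  put(4, c(SOL = 1.0, GAS = 0.7, ES = 0.4))
  W
}

#' Match synergies to a reference ordering
#'
#' Orders the candidate synergies against a reference set (or the default
#' phase templates) by greedily maximizing spatial-pattern cosine
#' similarity; ties are resolved by index.
#'
#' @param candidate A `synergy_set`.
#' @param reference A `synergy_set`, or a spatial matrix (muscles x N);
#'   defaults to [synergy_reference_templates()] on the candidate's muscles.
#' @return Integer permutation `p` such that candidate synergy `p[j]`
#'   corresponds to reference synergy `j`.
#' @export
match_synergies <- function(candidate, reference = NULL) {
  Wc <- candidate$W
  Wr <- if (is.null(reference)) {
    synergy_reference_templates(rownames(Wc))
  } else if (inherits(reference, "synergy_set")) reference$W else as.matrix(reference)
  if (ncol(Wc) != ncol(Wr)) {
    sts_error("candidate and reference have different synergy counts",
              "sts_validation_error")
  }
  cosine <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
  }
  S <- outer(seq_len(ncol(Wr)), seq_len(ncol(Wc)),
             Vectorize(function(j, k) cosine(Wr[, j], Wc[, k])))
  perm <- integer(ncol(Wr))
  used <- logical(ncol(Wc))
  # greedy: repeatedly take the globally best remaining (reference, candidate) pair
  for (step in seq_len(ncol(Wr))) {
    S_av <- S
    S_av[perm != 0, ] <- -Inf
    S_av[, used] <- -Inf
    ix <- which(S_av == max(S_av), arr.ind = TRUE)[1, ]
    perm[ix[1]] <- ix[2]
    used[ix[2]] <- TRUE
  }
  perm
}

#' Apply a synergy permutation
#'
#' @param synergies A `synergy_set`.
#' @param perm Permutation from [match_synergies()].
#' @return The reordered `synergy_set`.
#' @export
reorder_synergies <- function(synergies, perm) {
  synergies$W <- synergies$W[, perm, drop = FALSE]
  synergies$C <- synergies$C[perm, , drop = FALSE]
  synergies
}

#' Nonparametric longitudinal comparison of a feature
#'
#' Compares a per-trial feature between measurement days: the two-sided
#' Wilcoxon rank-sum test for two days, the Kruskal-Wallis test (one-way
#' analysis of variance on ranks) for three or more.
#'
#' @param values Numeric feature samples (one per trial).
#' @param days Grouping factor/vector of session days, same length.
#' @return List with `test` (`"wilcoxon_rank_sum"` or `"kruskal_wallis"`),
#'   `statistic`, `p_value`, `n_groups`.
#' @export
longitudinal_stats <- function(values, days) {
  days <- factor(days)
  if (length(values) != length(days)) {
    sts_error("values and days differ in length", "sts_validation_error")
  }
  counts <- table(days)
  if (length(counts) < 2L) {
    sts_error("need at least two measurement days", "sts_insufficient_data_error")
  }
  if (any(counts < 2L)) {
    sts_error("each day needs at least two trials", "sts_insufficient_data_error")
  }
  if (length(counts) == 2L) {
    lv <- levels(days)
    ht <- suppressWarnings(wilcox.test(values[days == lv[1]], values[days == lv[2]],
                                       exact = FALSE))
    list(test = "wilcoxon_rank_sum", statistic = unname(ht$statistic),
         p_value = ht$p.value, n_groups = 2L)
  } else {
    ht <- kruskal.test(values, days)
    list(test = "kruskal_wallis", statistic = unname(ht$statistic),
         p_value = ht$p.value, n_groups = length(counts))
  }
}

#' Percent change of a feature between first and last day
#'
#' `100 * (last - first) / first`, conventionally applied to the per-day
#' mean of per-trial maxima.
#'
#' @param feature_first,feature_last Scalar feature values (first and last
#'   measurement day).
#' @return Percent change.
#' @export
percent_change <- function(feature_first, feature_last) {
  if (feature_first == 0) {
    sts_error("percent change undefined for a zero baseline", "sts_degenerate_error")
  }
  100 * (feature_last - feature_first) / feature_first
}

#' @export
print.synergy_set <- function(x, ...) {
  cat(sprintf("Muscle synergy set: N = %d, reconstruction quality %.1f%%\n",
              x$N, x$reconstruction_quality))
  invisible(x)
}
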