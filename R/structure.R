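# Bayesian admixture clustering (STRUCTURE-style): a Gibbs sampler over
# allele-copy cluster assignments with Dirichlet(alpha) ancestry and
# Beta(lambda, lambda) allele-frequency priors, multi-run orchestration
# over a K grid, Evanno delta-K model choice, label-switching repair, and
# the 90%-membership pure/admixed classification rule.

#' Admixture-model Gibbs clustering of genotypes
#'
#' Runs the standard admixture model: each of an accession's two allele
#' copies per locus originates in one of K clusters with probability given
#' by the accession's ancestry vector Q; cluster allele frequencies P carry
#' a Beta(lambda, lambda) prior and ancestries a symmetric
#' Dirichlet(alpha) prior. A Gibbs cycle updates copy assignments, then P,
#' then Q. Post-burn-in means of Q and P are returned together with the
#' per-iteration log-likelihood trace and the model-evidence estimate
#' L(K) = mean(lnL) - var(lnL)/2. Missing genotypes contribute no
#' likelihood terms and are not imputed.
#'
#' Desk-scale defaults (2,000 burn-in / 5,000 iterations) stand in for the
#' 100,000/100,000 used by full-scale STRUCTURE analyses; pass those values
#' explicitly to reproduce them.
#'
#' @param gm a [genotype_matrix()] (biallelic loci).
#' @param K number of clusters (>= 1).
#' @param burnin,iterations Gibbs sweeps discarded / retained.
#' @param alpha Dirichlet ancestry hyperparameter (fixed, not sampled).
#' @param lambda Beta allele-frequency hyperparameter.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return a `q_run` object: `Q` (accessions x K, rows sum to 1), `P`
#'   (loci x K posterior mean alt frequencies), `trace` (lnL per retained
#'   iteration), `LK`, `K`, `seed`, `burnin`, `iterations`.
#' @export
admixture_gibbs <- function(gm, K, burnin = 2000, iterations = 5000,
                            alpha = 1.0, lambda = 1.0, seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (K < 1) stop("K must be >= 1")
  if (iterations < 1) stop("iterations must be >= 1")
  if (iterations < burnin)
    warning("fewer retained iterations than burn-in sweeps")
  if (!is.null(seed)) set.seed(seed)
  res <- admixture_gibbs_cpp(gm$geno, as.integer(K), as.integer(burnin),
                             as.integer(iterations), alpha, lambda)
  dimnames(res$Q) <- list(rownames(gm$geno), paste0("cluster", seq_len(K)))
  dimnames(res$P) <- list(colnames(gm$geno), paste0("cluster", seq_len(K)))
  lk <- mean(res$trace) - stats::var(res$trace) / 2
  structure(list(Q = res$Q, P = res$P, trace = res$trace, LK = lk,
                 K = as.integer(K), seed = seed,
                 burnin = as.integer(burnin),
                 iterations = as.integer(iterations)),
            class = "q_run")
}

#' @export
print.q_run <- function(x, ...) {
  cat(sprintf("<q_run> K = %d, %d accessions, L(K) = %.1f\n",
              x$K, nrow(x$Q), x$LK))
  invisible(x)
}

#' Run the clustering over a K grid with repeated seeded runs
#'
#' @inheritParams admixture_gibbs
#' @param K_min,K_max K grid bounds.
#' @param n_runs independent runs per K (>= 2 needed for Evanno).
#' @param seed master seed; run seeds are derived deterministically.
#' @return list of `q_run` objects (grouped by K, `n_runs` each).
#' @export
run_grid <- function(gm, K_min = 1, K_max = 10, n_runs = 10,
                     burnin = 2000, iterations = 5000, alpha = 1.0,
                     lambda = 1.0, seed = 1L) {
  if (K_min > K_max) stop("K_min must be <= K_max")
  if (n_runs < 1) stop("n_runs must be >= 1")
  runs <- list()
  for (K in K_min:K_max) {
    for (r in seq_len(n_runs)) {
      run_seed <- as.integer((as.numeric(seed) * 1000 + K * 100 + r) %%
                               .Machine$integer.max)
      runs[[length(runs) + 1L]] <-
        admixture_gibbs(gm, K, burnin = burnin, iterations = iterations,
                        alpha = alpha, lambda = lambda, seed = run_seed)
    }
  }
  runs
}

#' Evanno delta-K table and model choice
#'
#' Per K: mean and sd of L(K) across runs; L'(K) = mean L(K) - mean
#' L(K-1); L''(K) = |L'(K+1) - L'(K)|; delta K = L''(K) / sd(L(K)).
#' The selected K maximises delta K over interior K values. All-zero
#' second differences are flagged ambiguous.
#'
#' @param runs list of `q_run` objects covering >= 3 consecutive K values
#'   with >= 2 runs each.
#' @return list with `table` (data frame: K, n_runs, mean_LK, sd_LK,
#'   Lprime, Lsecond, deltaK), `K_selected`, `ambiguous`.
#' @export
evanno_delta_k <- function(runs) {
  ks <- vapply(runs, function(r) r$K, 0L)
  lks <- vapply(runs, function(r) r$LK, 0)
  kv <- sort(unique(ks))
  if (length(kv) < 3 || !all(diff(kv) == 1))
    stop("need >= 3 consecutive K values")
  if (any(table(ks) < 2)) stop("need >= 2 runs per K")
  mean_lk <- tapply(lks, ks, mean)[as.character(kv)]
  sd_lk <- tapply(lks, ks, stats::sd)[as.character(kv)]
  interior <- seq(2, length(kv) - 1)
  if (any(sd_lk[interior] == 0))
    stop("sd(L(K)) = 0 at an interior K: add runs or jitter seeds")
  lprime <- c(NA, diff(mean_lk))
  lsecond <- rep(NA_real_, length(kv))
  lsecond[interior] <- abs(lprime[interior + 1] - lprime[interior])
  deltak <- lsecond / sd_lk
  tab <- data.frame(K = kv, n_runs = as.integer(table(ks)[as.character(kv)]),
                    mean_LK = as.numeric(mean_lk),
                    sd_LK = as.numeric(sd_lk),
                    Lprime = lprime, Lsecond = lsecond,
                    deltaK = as.numeric(deltak), row.names = NULL)
  ambiguous <- all(tab$deltaK[interior] == 0)
  k_sel <- if (ambiguous) NA_integer_
           else tab$K[interior][which.max(tab$deltaK[interior])]
  list(table = tab, K_selected = k_sel, ambiguous = ambiguous)
}

#' Align cluster labels across runs of one K and average Q
#'
#' Greedy column matching to the first run, maximising the correlation
#' between matched Q columns (label-switching repair); returns the
#' permuted runs and the across-run average Q.
#'
#' @param runs list of `q_run` objects with equal K.
#' @return list with `runs` (aligned), `Q_mean`.
#' @export
align_runs <- function(runs) {
  ks <- vapply(runs, function(r) r$K, 0L)
  if (length(unique(ks)) != 1) stop("runs must share one K")
  K <- ks[1]
  ref <- runs[[1]]$Q
  aligned <- runs
  for (j in seq_along(runs)[-1]) {
    Q <- runs[[j]]$Q
    perm <- integer(K)
    cors <- suppressWarnings(stats::cor(ref, Q))
    cors[!is.finite(cors)] <- 0
    for (step in seq_len(K)) {
      best <- which(cors == max(cors), arr.ind = TRUE)[1, ]
      perm[best[1]] <- best[2]
      cors[best[1], ] <- -Inf
      cors[, best[2]] <- -Inf
    }
    aligned[[j]]$Q <- Q[, perm, drop = FALSE]
    aligned[[j]]$P <- runs[[j]]$P[, perm, drop = FALSE]
    colnames(aligned[[j]]$Q) <- colnames(ref)
    colnames(aligned[[j]]$P) <- colnames(ref)
  }
  q_mean <- Reduce(`+`, lapply(aligned, function(r) r$Q)) / length(aligned)
  list(runs = aligned, Q_mean = q_mean)
}

#' Classify accessions as genetically pure or admixed
#'
#' Accessions with membership to a single cluster strictly greater than
#' `pure_threshold` are pure; all others are admixed (membership exactly at
#' the threshold counts as admixed), with the majority cluster reported
#' when the maximum membership reaches `majority_threshold`.
#'
#' @param Q membership matrix (rows sum to 1), e.g. `run$Q` or an aligned
#'   average.
#' @param pure_threshold purity cut-off (default 0.90, strict `>`).
#' @param majority_threshold minimum membership for reporting a majority
#'   cluster for admixed accessions (default 0.50).
#' @return data frame: accession, status (`"pure"`/`"admixed"`), cluster
#'   (pure cluster or majority cluster, NA when below the majority
#'   threshold), max_membership.
#' @export
classify_membership <- function(Q, pure_threshold = 0.90,
                                majority_threshold = 0.50) {
  if (any(abs(rowSums(Q) - 1) > 1e-6)) stop("Q rows must sum to 1")
  maxm <- apply(Q, 1, max)
  maxk <- apply(Q, 1, which.max)
  cl <- colnames(Q)
  if (is.null(cl)) cl <- paste0("cluster", seq_len(ncol(Q)))
  status <- ifelse(maxm > pure_threshold, "pure", "admixed")
  cluster <- ifelse(maxm >= majority_threshold, cl[maxk], NA)
  data.frame(accession = if (!is.null(rownames(Q))) rownames(Q)
             else seq_len(nrow(Q)),
             status = status, cluster = cluster,
             max_membership = unname(maxm), row.names = NULL)
}

#' Write Q matrices in a STRUCTURE-like columnar layout
#'
#' @param run a `q_run` (or any object with a `Q` matrix).
#' @param path output path
#' @param pure_threshold threshold passed to [classify_membership()].
#' @return `path`, invisibly.
#' @export
write_q_matrix <- function(run, path, pure_threshold = 0.90) {
  Q <- if (is.matrix(run)) run else run$Q
  cls <- classify_membership(Q, pure_threshold)
  out <- data.frame(accession = cls$accession, assigned = cls$cluster,
                    status = cls$status, round(Q, 4))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
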