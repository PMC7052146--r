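# Morphological trait diversity: Shannon-Weiner indices, morphotype
# enumeration, private/diagnostic character detection, an AMOVA-style
# among/within variance partition on trait distances, trait-based PCoA
# with per-trait axis contributions, and morphology-genetics congruence.

as_morpho <- function(table) {
  tab <- as.data.frame(table)
  if (!"accession" %in% names(tab))
    stop("morphology table needs an 'accession' column")
  if (anyDuplicated(tab$accession)) stop("duplicate accession IDs")
  if (anyDuplicated(names(tab))) stop("trait names must be unique")
  tab
}

trait_columns <- function(tab) setdiff(names(tab), "accession")

# bin a quantitative trait into quantile classes for frequency-based indices
bin_quantitative <- function(x, bins = 4) {
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        na.rm = TRUE)
  qs <- unique(qs)
  if (length(qs) < 2) return(factor(rep("bin1", length(x)), exclude = NULL))
  cut(x, breaks = qs, include.lowest = TRUE,
      labels = paste0("bin", seq_len(length(qs) - 1)))
}

trait_states <- function(x, bins = 4) {
  if (is.numeric(x)) as.character(bin_quantitative(x, bins)) else as.character(x)
}

shannon_h <- function(states) {
  states <- states[!is.na(states)]
  if (!length(states)) return(NA_real_)
  p <- table(states) / length(states)
  -sum(p * log(p))
}

#' Shannon-Weiner diversity index per trait
#'
#' H' = -sum p_i ln(p_i) with p_i the frequency of the i-th character
#' state among non-missing observations. Quantitative traits are binned
#' into quantile classes first.
#'
#' @param table morphology data frame (`accession` column + one column per
#'   trait; categorical as character/factor, quantitative as numeric).
#' @param scope optional accession IDs restricting the computation (e.g.
#'   one species); default: whole cohort.
#' @param bins quantile bins for quantitative traits (default 4).
#' @return named numeric vector of per-trait H' (NA where a trait has no
#'   non-missing observation in scope).
#' @export
shannon_trait_index <- function(table, scope = NULL, bins = 4) {
  tab <- as_morpho(table)
  if (!is.null(scope)) tab <- tab[tab$accession %in% scope, , drop = FALSE]
  vapply(trait_columns(tab),
         function(tr) shannon_h(trait_states(tab[[tr]], bins)), 0)
}

#' Per-species morphological diversity (mean H' over traits)
#'
#' @param table morphology data frame (see [shannon_trait_index()]).
#' @param partition named accession -> species vector.
#' @param bins quantile bins for quantitative traits.
#' @return data frame: group, N, H (mean over traits), H_se (SE over
#'   traits), plus a `Total` row for the whole cohort.
#' @export
species_morph_diversity <- function(table, partition, bins = 4) {
  tab <- as_morpho(table)
  p <- stats::setNames(as.character(partition), names(partition))
  groups <- unique(p[tab$accession])
  one <- function(ids, label) {
    h <- shannon_trait_index(tab, scope = ids, bins = bins)
    data.frame(group = label, N = length(ids), H = mean(h, na.rm = TRUE),
               H_se = stats::sd(h, na.rm = TRUE) / sqrt(sum(!is.na(h))))
  }
  rows <- lapply(groups, function(g) one(tab$accession[p[tab$accession] == g], g))
  rbind(do.call(rbind, rows), one(tab$accession, "Total"))
}

#' Enumerate morphotypes (distinct complete character-state vectors)
#'
#' Two accessions share a morphotype iff their full state vectors are
#' equal. Accessions with any missing state are excluded from the
#' enumeration under the default complete-case policy.
#'
#' @inheritParams species_morph_diversity
#' @param complete_cases drop accessions with missing states (default
#'   TRUE).
#' @return list with `morphotypes` (data frame: morphotype ID, n_members,
#'   n_species, private, species list), `per_species` (data frame:
#'   group, n_morphotypes, n_private), `assignment` (accession ->
#'   morphotype ID), `n_excluded`.
#' @export
enumerate_morphotypes <- function(table, partition, complete_cases = TRUE) {
  tab <- as_morpho(table)
  p <- stats::setNames(as.character(partition), names(partition))
  traits <- trait_columns(tab)
  complete <- stats::complete.cases(tab[traits])
  n_excluded <- sum(!complete)
  if (complete_cases) tab <- tab[complete, , drop = FALSE]
  key <- apply(tab[traits], 1, paste, collapse = "\r")
  ids <- match(key, unique(key))
  mt_ids <- sprintf("MT%03d", ids)
  assignment <- stats::setNames(mt_ids, tab$accession)
  sp <- p[tab$accession]
  rows <- lapply(split(seq_len(nrow(tab)), mt_ids), function(ix) {
    species <- unique(sp[ix])
    data.frame(morphotype = mt_ids[ix[1]], n_members = length(ix),
               n_species = length(species),
               private = length(species) == 1,
               species = paste(sort(species), collapse = "+"))
  })
  morphotypes <- do.call(rbind, rows)
  rownames(morphotypes) <- NULL
  per_species <- do.call(rbind, lapply(unique(sp), function(g) {
    mts <- unique(mt_ids[sp == g])
    data.frame(group = g, n_morphotypes = length(mts),
               n_private = sum(morphotypes$private[
                 morphotypes$morphotype %in% mts] &
                 morphotypes$species[morphotypes$morphotype %in% mts] == g))
  }))
  list(morphotypes = morphotypes, per_species = per_species,
       assignment = assignment, n_excluded = n_excluded)
}

#' Private and diagnostic morphological characters per species
#'
#' A (trait, state) pair is private to species S when every non-missing
#' observation of S shows that state and no other species shows it;
#' diagnostic when the state occurs only in S but at frequency < 100%.
#'
#' @inheritParams species_morph_diversity
#' @param bins quantile bins for quantitative traits.
#' @return data frame: trait, state, species, status
#'   (`"private"`/`"diagnostic"`), freq_in_carrier.
#' @export
private_diagnostic_characters <- function(table, partition, bins = 4) {
  tab <- as_morpho(table)
  p <- stats::setNames(as.character(partition), names(partition))
  sp <- p[tab$accession]
  species <- unique(sp)
  out <- list()
  for (tr in trait_columns(tab)) {
    states <- trait_states(tab[[tr]], bins)
    for (st in unique(stats::na.omit(states))) {
      carriers <- unique(sp[!is.na(states) & states == st])
      if (length(carriers) != 1) next
      g <- carriers
      obs <- states[sp == g & !is.na(states)]
      freq <- mean(obs == st)
      out[[length(out) + 1L]] <- data.frame(
        trait = tr, state = st, species = g,
        status = if (freq >= 1) "private" else "diagnostic",
        freq_in_carrier = freq)
    }
  }
  if (!length(out))
    return(data.frame(trait = character(), state = character(),
                      species = character(), status = character(),
                      freq_in_carrier = numeric()))
  do.call(rbind, out)
}

#' Gower distance over mixed morphological traits
#'
#' Categorical traits contribute 0/1 mismatch, quantitative traits the
#' range-normalised absolute difference (cluster::daisy). An
#' integer-coded Euclidean alternative is available.
#'
#' @inheritParams species_morph_diversity
#' @param method `"gower"` (default) or `"euclidean"` (categorical states
#'   integer-coded).
#' @return a `gbs_dist` over accessions.
#' @export
morpho_distance <- function(table, method = c("gower", "euclidean")) {
  tab <- as_morpho(table)
  method <- match.arg(method)
  traits <- trait_columns(tab)
  df <- tab[traits]
  for (tr in traits)
    if (!is.numeric(df[[tr]])) df[[tr]] <- factor(df[[tr]])
  if (method == "gower") {
    d <- cluster::daisy(df, metric = "gower", warnBin = FALSE,
                        warnAsym = FALSE, warnConst = FALSE)
  } else {
    num <- as.data.frame(lapply(df, function(x)
      if (is.numeric(x)) x else as.integer(x)))
    d <- stats::dist(num)
  }
  m <- as.matrix(d)
  dimnames(m) <- list(tab$accession, tab$accession)
  new_distance_matrix(m, paste0("morpho_", method))
}

#' Among/within-species variance partition of trait distances
#'
#' AMOVA-style sums-of-squares partition of the pairwise trait-distance
#' matrix: SS(total) over all pairs, SS(within) over within-group pairs;
#' variance components and their percentages follow the standard
#' distance-AMOVA estimators, with significance from permuting group
#' labels (pseudo-F statistic).
#'
#' @param d a `gbs_dist` (e.g. [morpho_distance()]) or symmetric matrix.
#' @param partition named accession -> group vector.
#' @param n_perm label permutations for the P value (default 999).
#' @param seed integer seed.
#' @return list with `pct_among`, `pct_within`, `p_value`, `ss` (data
#'   frame of SS/df), `phi` (among-group fixation analogue).
#' @export
variance_partition <- function(d, partition, n_perm = 999, seed = 1L) {
  m <- if (inherits(d, "gbs_dist")) d$matrix else as.matrix(d)
  ids <- rownames(m)
  p <- stats::setNames(as.character(partition), names(partition))[ids]
  if (anyNA(p)) stop("partition does not cover all entities")
  groups <- unique(p)
  n <- nrow(m)
  if (any(table(p) == 1))
    warning("group(s) of size 1 contribute no within-group term")
  comp <- function(p) {
    ss_total <- sum(m[upper.tri(m)]^2) / n
    ss_within <- 0
    for (g in unique(p)) {
      ix <- which(p == g)
      if (length(ix) > 1) {
        sub <- m[ix, ix]
        ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / length(ix)
      }
    }
    ss_among <- ss_total - ss_within
    df_among <- length(unique(p)) - 1
    df_within <- n - length(unique(p))
    ms_among <- ss_among / df_among
    ms_within <- ss_within / df_within
    ng <- table(p)
    n0 <- (n - sum(ng^2) / n) / df_among
    sigma_within <- ms_within
    sigma_among <- max((ms_among - ms_within) / n0, 0)
    list(ss_total = ss_total, ss_within = ss_within, ss_among = ss_among,
         df_among = df_among, df_within = df_within,
         f = ms_among / ms_within,
         sigma_among = sigma_among, sigma_within = sigma_within)
  }
  obs <- comp(p)
  set.seed(seed)
  perm_f <- vapply(seq_len(n_perm), function(r)
    comp(sample(p))$f, 0)
  p_value <- (sum(perm_f >= obs$f) + 1) / (n_perm + 1)
  tot <- obs$sigma_among + obs$sigma_within
  list(pct_among = 100 * obs$sigma_among / tot,
       pct_within = 100 * obs$sigma_within / tot,
       p_value = p_value,
       ss = data.frame(source = c("among", "within", "total"),
                       ss = c(obs$ss_among, obs$ss_within, obs$ss_total),
                       df = c(obs$df_among, obs$df_within, n - 1)),
       phi = obs$sigma_among / tot)
}

#' PCoA of morphology with per-trait axis contributions
#'
#' Runs [pcoa()] on the mixed-trait Gower distance and scores each trait's
#' contribution to each axis as the squared correlation (for quantitative
#' traits) or the ANOVA R-squared (for categorical traits) between the
#' trait and the axis coordinates, normalised to percent per axis.
#'
#' @inheritParams morpho_distance
#' @param k number of axes for the contribution table (default 3).
#' @return list with the [pcoa()] fields plus `contributions` (traits x
#'   axes, percent per axis).
#' @export
morpho_ordination <- function(table, method = "gower", k = 3) {
  tab <- as_morpho(table)
  d <- morpho_distance(tab, method = method)
  ord <- pcoa(d)
  k <- min(k, ncol(ord$coordinates))
  traits <- trait_columns(tab)
  contrib <- matrix(NA_real_, length(traits), k,
                    dimnames = list(traits, colnames(ord$coordinates)[seq_len(k)]))
  for (j in seq_len(k)) {
    ax <- ord$coordinates[, j]
    for (tr in traits) {
      x <- tab[[tr]]
      r2 <- if (is.numeric(x)) {
        suppressWarnings(stats::cor(x, ax, use = "complete.obs"))^2
      } else {
        f <- factor(x)
        ok <- !is.na(f)
        if (nlevels(droplevels(f[ok])) < 2) 0
        else {
          # one-way ANOVA R^2 of axis scores on the trait factor
          y <- ax[ok]; g <- droplevels(f[ok])
          sst <- sum((y - mean(y))^2)
          gm <- tapply(y, g, mean)
          ssb <- sum(table(g) * (gm - mean(y))^2)
          if (sst > 0) ssb / sst else 0
        }
      }
      contrib[tr, j] <- if (is.finite(r2)) r2 else 0
    }
    contrib[, j] <- 100 * contrib[, j] / sum(contrib[, j])
  }
  c(ord, list(contributions = contrib))
}

#' Morphology-genetics congruence (Mantel)
#'
#' Mantel test between a morphological and a genetic distance matrix over
#' the shared accession set (delegates to [mantel_test()]).
#'
#' @param morpho_dist,genetic_dist `gbs_dist` or symmetric matrices.
#' @inheritParams mantel_test
#' @return as [mantel_test()].
#' @export
morpho_genetic_congruence <- function(morpho_dist, genetic_dist,
                                      n_perm = 999, seed = 1L) {
  mantel_test(morpho_dist, genetic_dist, n_perm = n_perm, seed = seed)
}
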