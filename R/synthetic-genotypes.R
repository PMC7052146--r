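# Synthetic cohort generator. Species diverge from shared ancestral allele
# frequencies under a Balding-Nichols drift model (coefficient F per
# species); genotypes are drawn with a heterozygote deficit matching a
# target Fis; a configurable fraction of loci per species is forced
# private-fixed (fixed for an allele absent in every other species), so the
# downstream allele classifier can be validated against recorded truth.

#' Configuration for the synthetic multi-species cohort
#'
#' Defaults emulate the sampled design of a seven-species GBS diversity
#' study: 86 accessions in seven uneven species samples scored at 3002
#' biallelic SNPs, strong divergence, substantial within-species
#' inbreeding, and a modest fraction of private-fixed loci per species.
#'
#' @param n_species number of species.
#' @param n_per_species accession count per species (recycled if scalar).
#' @param n_loci number of biallelic SNP loci.
#' @param F_divergence Balding-Nichols drift coefficient per species, in
#'   `[0, 1)`; scalar or one value per species.
#' @param inbreeding within-species Fis target in `[0, 1]`: each genotype is
#'   drawn autozygous (one allele copied) with this probability, else from
#'   Hardy-Weinberg, so E[Fis] equals the parameter exactly.
#' @param private_fixed_fraction fraction of loci forced private-fixed per
#'   species (blocks are disjoint across species).
#' @param missing_rate per-genotype-call missing probability.
#' @param n_low_read number of accessions given a low simulated read count
#'   and `low_read_multiplier` times the missing rate (exercises sample QC).
#' @param low_read_multiplier missing-rate multiplier for low-read
#'   accessions.
#' @param cline_strength longitude-vs-genetic-structure coupling in `[0,1]`
#'   used by [assign_geography()].
#' @param seed integer seed fixing all generator output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_species = 7,
                       n_per_species = c(6, 3, 13, 13, 17, 8, 26),
                       n_loci = 3002,
                       F_divergence = 0.85,
                       inbreeding = 0.45,
                       private_fixed_fraction = 0.04,
                       missing_rate = 0.10,
                       n_low_read = 0,
                       low_read_multiplier = 4,
                       cline_strength = 0.6,
                       seed = 1L) {
  if (n_species < 1) stop("n_species must be >= 1")
  n_per_species <- rep_len(n_per_species, n_species)
  if (any(n_per_species < 1)) stop("every species needs >= 1 accession")
  if (n_loci < 1) stop("n_loci must be >= 1")
  F_divergence <- rep_len(F_divergence, n_species)
  rates <- c(F_divergence, inbreeding, private_fixed_fraction, missing_rate,
             cline_strength)
  if (any(rates < 0 | rates > 1) || any(F_divergence >= 1))
    stop("all rates must lie in [0, 1] (F_divergence in [0, 1))")
  if (round(private_fixed_fraction * n_loci) * n_species > n_loci)
    stop("private_fixed_fraction too large for n_loci and n_species")
  structure(list(n_species = as.integer(n_species),
                 n_per_species = as.integer(n_per_species),
                 n_loci = as.integer(n_loci),
                 F_divergence = F_divergence, inbreeding = inbreeding,
                 private_fixed_fraction = private_fixed_fraction,
                 missing_rate = missing_rate,
                 n_low_read = as.integer(n_low_read),
                 low_read_multiplier = low_read_multiplier,
                 cline_strength = cline_strength,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Balding-Nichols draw of descendant frequencies around ancestral p with
# drift coefficient F; F = 0 returns p unchanged.
rbalding_nichols <- function(p, F) {
  if (F == 0) return(p)
  shape <- (1 - F) / F
  stats::rbeta(length(p), p * shape, (1 - p) * shape)
}

# draw diploid genotypes (alt dosage) for one species: autozygous with
# probability fis (one allele copied), else two independent allele draws
draw_genotypes <- function(n, p, fis) {
  L <- length(p)
  pm <- matrix(p, n, L, byrow = TRUE)
  auto <- matrix(stats::runif(n * L) < fis, n, L)
  a1 <- matrix(stats::runif(n * L) < pm, n, L)
  a2 <- matrix(stats::runif(n * L) < pm, n, L)
  a2[auto] <- a1[auto]
  g <- a1 + a2
  storage.mode(g) <- "integer"
  g
}

#' Simulate a multi-species genotype cohort with recorded ground truth
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (a [genotype_matrix()]) and `truth`, a list
#'   holding `ancestral` (per-locus ancestral frequencies), `species_freq`
#'   (loci x species alternate-allele frequencies), `species` (named
#'   accession -> species vector), `admixture` (accessions x species, rows
#'   sum to 1), `private_loci` (list of injected private-fixed locus IDs per
#'   species) and `coords` (`NULL` until [assign_geography()] runs).
#' @export
simulate_species_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  S <- config$n_species; L <- config$n_loci
  species_names <- sprintf("sp%02d", seq_len(S))

  p_anc <- stats::runif(L, 0.1, 0.9)
  freq <- vapply(seq_len(S),
                 function(s) rbalding_nichols(p_anc, config$F_divergence[s]),
                 numeric(L))

  locus_ids <- sprintf("M%04d", seq_len(L))
  n_priv <- round(config$private_fixed_fraction * L)
  private_loci <- stats::setNames(vector("list", S), species_names)
  if (n_priv > 0) {
    for (s in seq_len(S)) {
      idx <- ((s - 1) * n_priv + 1):(s * n_priv)
      freq[idx, ] <- 0        # alt absent everywhere ...
      freq[idx, s] <- 1       # ... except fixed in the carrier species
      private_loci[[s]] <- locus_ids[idx]
    }
  }

  geno <- do.call(rbind, lapply(seq_len(S), function(s)
    draw_genotypes(config$n_per_species[s], freq[, s], config$inbreeding)))
  acc_ids <- unlist(lapply(seq_len(S), function(s)
    sprintf("%s_%02d", toupper(species_names[s]), seq_len(config$n_per_species[s]))))
  species <- stats::setNames(rep(species_names, config$n_per_species), acc_ids)
  N <- length(acc_ids)

  reads <- round(stats::rlnorm(N, meanlog = log(1.6e6), sdlog = 0.45))
  miss_mult <- rep(1, N)
  if (config$n_low_read > 0) {
    low <- sample(N, config$n_low_read)
    miss_mult[low] <- config$low_read_multiplier
    reads[low] <- round(stats::runif(config$n_low_read, 2e5, 5.9e5))
  }
  if (config$missing_rate > 0) {
    pm <- pmin(outer(miss_mult, rep(config$missing_rate, L)), 1)
    geno[matrix(stats::runif(N * L), N, L) < pm] <- NA_integer_
  }

  alleles <- t(vapply(seq_len(L), function(i) sample(c("A", "C", "G", "T"), 2),
                      character(2)))
  loci <- data.frame(locus = locus_ids,
                     tag = sprintf("T%05d", seq_len(L)),
                     pos = sample(5:60, L, replace = TRUE),
                     qd = round(stats::rlnorm(L, log(25), 0.4), 2),
                     ref = alleles[, 1], alt = alleles[, 2],
                     n_alleles = 2L)
  rownames(geno) <- acc_ids
  colnames(geno) <- locus_ids
  accessions <- data.frame(accession = acc_ids,
                           species = unname(species),
                           subgenus = ifelse(match(species, species_names) <=
                                               ceiling(S / 2), "sgA", "sgB"),
                           lat = NA_real_, lon = NA_real_, reads = reads)
  admix <- matrix(0, N, S, dimnames = list(acc_ids, species_names))
  admix[cbind(seq_len(N), match(species, species_names))] <- 1

  truth <- list(ancestral = p_anc,
                species_freq = `dimnames<-`(freq, list(locus_ids, species_names)),
                species = species, admixture = admix,
                private_loci = private_loci, coords = NULL,
                config = config)
  list(matrix = genotype_matrix(geno, loci = loci, accessions = accessions),
       truth = truth)
}

#' Assign geographic coordinates with a longitudinal cline
#'
#' Species are ordered along a longitudinal (East-West) transect according
#' to their genetic similarity (first principal coordinate of the
#' between-species frequency distance), so that geographic distance
#' correlates with genetic distance; `cline_strength` interpolates between
#' fully random longitudes (0) and perfect species-level ordering (1).
#'
#' @param truth truth list from [simulate_species_genotypes()].
#' @param cline_strength coupling in `[0, 1]`; default taken from the
#'   generating config.
#' @param jitter_sd within-species longitudinal jitter, decimal degrees.
#' @param lon_range,lat_range sampled geographic window (default spans
#'   roughly 44-62 E / 27-39 N, a country-scale East-West transect).
#' @param seed integer seed.
#' @return `truth` with a `coords` data frame (accession, lat, lon) added.
#' @export
assign_geography <- function(truth, cline_strength = truth$config$cline_strength,
                             jitter_sd = 0.2, lon_range = c(44, 62),
                             lat_range = c(27, 39), seed = truth$config$seed + 1L) {
  if (is.null(truth$species)) stop("truth lacks species assignments")
  if (cline_strength < 0 || cline_strength > 1)
    stop("cline_strength must lie in [0, 1]")
  set.seed(seed)
  species_names <- colnames(truth$species_freq)
  S <- length(species_names)
  if (S > 1) {
    d <- stats::dist(t(truth$species_freq))
    ord <- order(stats::cmdscale(d, k = 1)[, 1])
  } else ord <- 1L
  base <- stats::setNames(numeric(S), species_names)
  base[species_names[ord]] <- if (S > 1)
    seq(lon_range[1] + 1, lon_range[2] - 1, length.out = S) else mean(lon_range)

  acc <- names(truth$species)
  n <- length(acc)
  lon <- cline_strength * base[truth$species] +
    (1 - cline_strength) * stats::runif(n, lon_range[1], lon_range[2]) +
    stats::rnorm(n, 0, jitter_sd)
  lat <- stats::runif(n, lat_range[1], lat_range[2])
  truth$coords <- data.frame(accession = acc, lat = lat,
                             lon = unname(lon), row.names = NULL)
  truth
}

#' Attach simulated coordinates to a genotype matrix
#'
#' @param gm a [genotype_matrix()]
#' @param truth a truth list carrying `coords`.
#' @return the matrix with `lat`/`lon` metadata filled in.
#' @export
apply_geography <- function(gm, truth) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(truth$coords)) stop("run assign_geography() first")
  i <- match(gm$accessions$accession, truth$coords$accession)
  gm$accessions$lat <- truth$coords$lat[i]
  gm$accessions$lon <- truth$coords$lon[i]
  gm
}

#' Simulate an interspecific hybrid accession
#'
#' The two allele-copy origins per locus follow an F1/backcross scheme
#' honouring the target ancestry: at `proportion = 0.5` every locus takes
#' one copy from each parent (a true F1, so parents fixed for opposite
#' alleles yield 100% heterozygosity); at `proportion` p > 0.5 a locus is
#' (A, A) with probability 2p - 1 and (A, B) otherwise, and symmetrically
#' for p < 0.5, so the expected genome fraction from parent A is exactly
#' p. Allele values are drawn from the parents' allele-frequency pools.
#' When the parents are diverged, the resulting accession is heterozygous
#' at far more loci than any within-species accession.
#'
#' @param truth truth list from [simulate_species_genotypes()].
#' @param parent_a,parent_b species labels present in the truth.
#' @param proportion ancestry fraction from `parent_a`, strictly in (0, 1).
#' @param seed integer seed.
#' @param id accession ID for the hybrid.
#' @return list with `geno` (named integer dosage vector), `id`, and
#'   `admixture` (named ancestry proportions).
#' @export
simulate_hybrid <- function(truth, parent_a, parent_b, proportion = 0.5,
                            seed = truth$config$seed + 2L, id = "HYB_01") {
  sp <- colnames(truth$species_freq)
  if (!all(c(parent_a, parent_b) %in% sp))
    stop("both parents must be simulated species")
  if (proportion <= 0 || proportion >= 1)
    stop("proportion must lie strictly in (0, 1)")
  set.seed(seed)
  L <- nrow(truth$species_freq)
  pa <- truth$species_freq[, parent_a]
  pb <- truth$species_freq[, parent_b]
  # copy-origin pairs: both-from-majority-parent with prob |2p - 1|,
  # else one copy from each parent
  both_major <- stats::runif(L) < abs(2 * proportion - 1)
  major <- if (proportion >= 0.5) pa else pb
  p1 <- ifelse(both_major, major, pa)
  p2 <- ifelse(both_major, major, pb)
  g <- as.integer(stats::runif(L) < p1) + as.integer(stats::runif(L) < p2)
  names(g) <- rownames(truth$species_freq)
  adm <- stats::setNames(numeric(length(sp)), sp)
  adm[parent_a] <- proportion; adm[parent_b] <- adm[parent_b] + 1 - proportion
  list(geno = g, id = id, admixture = adm)
}

#' Append an accession (e.g. a simulated hybrid) to a genotype matrix
#'
#' @param gm a [genotype_matrix()]
#' @param id accession ID
#' @param geno integer dosage vector matching the matrix's loci.
#' @param species,subgenus,lat,lon,reads metadata for the new accession.
#' @return the extended `genotype_matrix`.
#' @export
bind_accession <- function(gm, id, geno, species = NA, subgenus = NA,
                           lat = NA, lon = NA, reads = NA) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (length(geno) != ncol(gm$geno)) stop("genotype length mismatch")
  if (!is.null(names(geno))) geno <- geno[colnames(gm$geno)]
  g <- rbind(gm$geno, geno)
  rownames(g)[nrow(g)] <- id
  new_vals <- list(accession = id, species = species, subgenus = subgenus,
                   lat = lat, lon = lon, reads = reads)
  meta <- gm$accessions[1, , drop = FALSE]
  meta[1, ] <- NA
  for (nm in names(meta))
    meta[[nm]] <- if (nm %in% names(new_vals)) new_vals[[nm]] else NA
  genotype_matrix(g, loci = gm$loci, accessions = rbind(gm$accessions, meta))
}
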