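# Species-determined categorical morphology: every accession inherits its
# species' modal character state per trait and flips to an alternative
# state with a per-trait noise rate. States designed private to a species
# are never available as flip targets elsewhere, so designed private
# characters stay private at any noise level.

#' Default 16-trait morphology specification
#'
#' Builds a trait specification over the classic foxtail-lily descriptor
#' set (inflorescence/stem/leaf measures scored as classes, rhizome and
#' peduncle descriptors, and the flower characters tepal color, tepal
#' nerve, tepal tip, flower shape, bract margin, fruit shape, and leaf
#' indumentum). The three flower traits tepal color, tepal tip and flower
#' shape jointly differentiate every species, and a subset of species is
#' given designed-private states (tepal color states exist only in their
#' carrier).
#'
#' @param species character vector of species labels.
#' @param n_private_species how many species receive a designed-private
#'   tepal-color state (default `min(4, length(species))`).
#' @param seed integer seed controlling modal-state assignment.
#' @return list of trait definitions; each has `name`, `states`, `modal`
#'   (named per-species modal state) and optional `private` (named
#'   species -> state).
#' @export
default_trait_spec <- function(species, n_private_species = min(4L, length(species)),
                               seed = 100L) {
  set.seed(seed)
  S <- length(species)
  trait_names <- c("inflorescence_length", "stem_length", "leaf_length",
                   "leaf_number", "stem_diameter", "rhizome_number",
                   "rhizome_diameter", "peduncle_length", "tepal_color",
                   "tepal_nerve", "tepal_tip", "flower_shape", "bract_margin",
                   "fruit_shape", "leaf_margin_indumentum",
                   "leaf_surface_indumentum")
  spec <- vector("list", length(trait_names))
  names(spec) <- trait_names
  for (tn in trait_names) {
    if (tn == "tepal_color") {
      shared <- c("white", "yellow", "pink")
      priv_states <- paste0("color_", seq_len(n_private_species))
      carriers <- species[seq_len(n_private_species)]
      states <- c(shared, priv_states)
      modal <- stats::setNames(rep(shared, length.out = S), species)
      modal[carriers] <- priv_states
      private <- stats::setNames(priv_states, carriers)
    } else if (tn %in% c("tepal_tip", "flower_shape")) {
      # enough states that (tepal_color, tepal_tip, flower_shape) jointly
      # separate all species
      states <- paste0(tn, "_s", seq_len(max(3, ceiling(S / 2))))
      modal <- stats::setNames(states[((seq_len(S) - 1) %% length(states)) + 1],
                               species)
      if (tn == "flower_shape")
        modal <- stats::setNames(states[((seq_len(S)) %% length(states)) + 1],
                                 species)
      private <- NULL
    } else {
      k <- sample(2:4, 1)
      states <- paste0(tn, "_s", seq_len(k))
      modal <- stats::setNames(sample(states, S, replace = TRUE), species)
      private <- NULL
    }
    spec[[tn]] <- list(name = tn, states = states, modal = modal,
                       private = private)
  }
  spec
}

#' Simulate a morphology table from species-modal trait states
#'
#' @param truth truth list from [simulate_species_genotypes()] (uses the
#'   species assignment), or any named accession -> species vector passed
#'   via `species`.
#' @param trait_spec output of [default_trait_spec()] (or the same shape).
#' @param noise_rates per-trait flip probability in `[0, 1]`; scalar or one
#'   value per trait.
#' @param seed integer seed.
#' @param species optional named accession -> species vector overriding
#'   `truth$species`.
#' @return list with `table` (data frame, accessions x traits, first column
#'   `accession`) and `truth` (`private_characters` data frame of designed
#'   (trait, state, species) rows).
#' @export
simulate_morphology <- function(truth = NULL, trait_spec, noise_rates = 0.05,
                                seed = 3L, species = truth$species) {
  if (is.null(species)) stop("species assignments required")
  noise_rates <- rep_len(noise_rates, length(trait_spec))
  if (any(noise_rates < 0 | noise_rates > 1))
    stop("noise rates must lie in [0, 1]")
  set.seed(seed)
  acc <- names(species)
  out <- data.frame(accession = acc)
  priv_rows <- list()
  for (j in seq_along(trait_spec)) {
    tr <- trait_spec[[j]]
    vals <- unname(tr$modal[species])
    flip <- stats::runif(length(acc)) < noise_rates[j]
    if (any(flip)) {
      for (i in which(flip)) {
        sp_i <- species[i]
        # flip targets: any state not designed private to another species
        banned <- if (!is.null(tr$private))
          tr$private[setdiff(names(tr$private), sp_i)] else character()
        alt <- setdiff(tr$states, c(vals[i], banned))
        if (length(alt)) vals[i] <- sample(alt, 1)
      }
    }
    out[[tr$name]] <- vals
    if (!is.null(tr$private))
      priv_rows[[tr$name]] <- data.frame(trait = tr$name,
                                         state = unname(tr$private),
                                         species = names(tr$private))
  }
  list(table = out,
       truth = list(private_characters = do.call(rbind, priv_rows)))
}
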