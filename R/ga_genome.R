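# Genome encoding of an omnivariate tree configuration: per internal slot a
# prune bit, a 2-bit family index and two hyperparameter grid indices.
# The genome <-> specification mapping is an exact bijection: raw indices are
# kept in the spec, and interpretation into grid values (modulo the family's
# grid size) happens separately.

.GENES_PER_SLOT <- 4L
# number of levels of each gene within a slot: prune, family, hp1, hp2
.GENE_LEVELS <- c(2L, 4L, 4L, 3L)

#' Gene-level layout of a GA genome
#'
#' @param config An [omni_tree_config()].
#' @return Integer vector giving the number of admissible levels of every
#'   gene (values run `0 .. levels - 1`); its length is the genome length.
#' @export
genome_levels <- function(config = omni_tree_config()) {
  rep(.GENE_LEVELS, .n_slots(config))
}

#' Resolve a slot's raw hyperparameter indices into grid values
#'
#' Family index 0..3 maps, in fixed order, to univariate_tree, neural_net,
#' random_forest, multinomial_logistic; raw indices are folded into each
#' family's grid by modulo.
#'
#' @param family_idx Integer 0..3.
#' @param hp1,hp2 Raw indices (0-based).
#' @return List with `family` and resolved `hyperparams`.
#' @export
resolve_node_spec <- function(family_idx, hp1, hp2) {
  grids <- node_family_grids()
  family <- .NODE_FAMILIES[family_idx + 1L]
  hp <- switch(family,
    univariate_tree = list(confidence =
      grids$univariate_tree$confidence[(hp1 %% 3L) + 1L]),
    neural_net = list(hidden = grids$neural_net$hidden[(hp1 %% 4L) + 1L]),
    random_forest = list(
      n_trees = grids$random_forest$n_trees[(hp1 %% 4L) + 1L],
      mtry = grids$random_forest$mtry[(hp2 %% 3L) + 1L]),
    multinomial_logistic = list(ridge =
      grids$multinomial_logistic$ridge[(hp1 %% 3L) + 1L]))
  list(family = family, hyperparams = hp)
}

#' Decode a genome into per-slot node specifications
#'
#' @param genome Integer vector of length `4 * (2^max_depth - 1)`.
#' @param config An [omni_tree_config()].
#' @return List with one entry per internal slot: `prune` (logical),
#'   `family`, raw `hp1`/`hp2` indices and resolved `hyperparams`.
#' @export
decode_genome <- function(genome, config = omni_tree_config()) {
  levels <- genome_levels(config)
  if (length(genome) != length(levels)) {
    stop("decode_genome: genome length ", length(genome), " != expected ",
         length(levels))
  }
  if (any(genome < 0L | genome >= levels)) {
    stop("decode_genome: gene value out of range")
  }
  lapply(seq_len(.n_slots(config)), function(s) {
    g <- genome[(s - 1L) * .GENES_PER_SLOT + 1:4]
    rs <- resolve_node_spec(g[2], g[3], g[4])
    list(prune = g[1] == 1L, family = rs$family,
         hp1 = as.integer(g[3]), hp2 = as.integer(g[4]),
         hyperparams = rs$hyperparams)
  })
}

#' Encode per-slot node specifications back into a genome
#'
#' Exact inverse of [decode_genome()]: `encode_genome(decode_genome(g)) == g`
#' and `decode_genome(encode_genome(spec))` reproduces `spec`.
#'
#' @param spec List of slot specifications (see [decode_genome()]).
#' @param config An [omni_tree_config()].
#' @return Integer genome.
#' @export
encode_genome <- function(spec, config = omni_tree_config()) {
  stopifnot(length(spec) == .n_slots(config))
  unlist(lapply(spec, function(s) {
    c(as.integer(s$prune), match(s$family, .NODE_FAMILIES) - 1L,
      s$hp1, s$hp2)
  }))
}

#' Draw a uniformly random genome
#'
#' @param config An [omni_tree_config()].
#' @return Integer genome with each gene uniform over its levels. Uses the
#'   current RNG stream.
#' @export
random_genome <- function(config = omni_tree_config()) {
  levels <- genome_levels(config)
  vapply(levels, function(l) sample.int(l, 1L) - 1L, integer(1))
}

# count of unpruned internal slots (simplicity measure for fitness ties)
.n_active <- function(genome, config) {
  sum(genome[seq(1L, length(genome), by = .GENES_PER_SLOT)] == 0L)
}
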