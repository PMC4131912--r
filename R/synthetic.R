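#' Configuration for the synthetic benchmark generator
#'
#' Describes a species complex with the statistical structure the
#' delimitation pipeline assumes: `k_species` separated by a barcode gap,
#' coalescent variation among individuals within species, shallow
#' intra-genomic variation among rDNA copies (clones) of one individual,
#' heterogeneous lineage rates, and optionally degraded sequences.
#'
#' Divergences are expected substitutions per site between tip pairs:
#' `coal_depth` is the within-species ceiling, `intragenomic_div` the
#' clone-to-clone ceiling, and the smallest between-species divergence is
#' `gap_factor * coal_depth`.
#'
#' @param seed Integer seed; every random draw flows from it.
#' @param k_species Number of true species (default 5).
#' @param n_individuals Individuals sequenced per species (default 5).
#' @param clones_range Integer range of clones per individual (default
#'   `c(2, 7)`, matching typical cloning depth).
#' @param species_tree_rate Yule speciation rate shaping the species-tree
#'   topology (default 1; ages are rescaled afterwards, so only the shape
#'   matters).
#' @param coal_depth Expected maximum within-species divergence (default
#'   0.01, i.e. 1%).
#' @param gap_factor Ratio of the smallest between-species divergence to
#'   `coal_depth` (default 10; must exceed 1).
#' @param root_spread Ratio of the deepest to the shallowest species
#'   divergence (default 3).
#' @param rate_sdlog Log-normal sd of per-species lineage rate multipliers
#'   (default 0.25; 0 disables rate heterogeneity).
#' @param intragenomic_div Expected clone-to-clone divergence within one
#'   individual (default 0.003).
#' @param kappa Transition/transversion rate ratio of the K80 substitution
#'   process (default 2).
#' @param seq_length Simulated sequence length in bp (default 700, the
#'   homologous-block scale).
#' @param degrade List with `short_fraction`, `trunc_length`,
#'   `five_prime_fraction`, `five_prime_error_rate` controlling sequence
#'   degradation (all off by default).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, k_species = 5, n_individuals = 5,
                       clones_range = c(2, 7), species_tree_rate = 1,
                       coal_depth = 0.01, gap_factor = 10, root_spread = 3,
                       rate_sdlog = 0.25, intragenomic_div = 0.003,
                       kappa = 2, seq_length = 700,
                       degrade = list(short_fraction = 0, trunc_length = 400,
                                      five_prime_fraction = 0,
                                      five_prime_error_rate = 0.05)) {
  stopifnot(seed == as.integer(seed), abs(seed) < 2^31 - 10,
            k_species >= 1, n_individuals >= 1,
            length(clones_range) == 2, clones_range[1] >= 1,
            clones_range[2] >= clones_range[1],
            gap_factor > 1, coal_depth > 0, intragenomic_div >= 0,
            intragenomic_div < coal_depth, root_spread >= 1,
            rate_sdlog >= 0, kappa > 0, seq_length >= 1)
  structure(list(seed = as.integer(seed), k_species = k_species,
                 n_individuals = n_individuals, clones_range = clones_range,
                 species_tree_rate = species_tree_rate,
                 coal_depth = coal_depth, gap_factor = gap_factor,
                 root_spread = root_spread, rate_sdlog = rate_sdlog,
                 intragenomic_div = intragenomic_div, kappa = kappa,
                 seq_length = seq_length, degrade = degrade),
            class = "sim_config")
}

# linearly remap internal node ages onto [lo, hi] (order preserved) and
# rebuild edge lengths; tips stay at age 0
remap_node_ages <- function(tree, lo, hi) {
  n <- length(tree$tip.label)
  ages <- node_ages(tree)
  internal <- (n + 1):(n + tree$Nnode)
  a <- ages[internal]
  new_a <- if (max(a) - min(a) < .Machine$double.eps * max(a, 1)) {
    rep(hi, length(a))
  } else {
    lo + (a - min(a)) / (max(a) - min(a)) * (hi - lo)
  }
  ages[internal] <- new_a
  ages[seq_len(n)] <- 0
  tree$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  tree
}

scale_to_height <- function(tree, h) {
  cur <- max(node_ages(tree))
  tree$edge.length <- tree$edge.length * (h / cur)
  tree
}

# replace a backbone tip with an ultrametric subtree of the given height;
# the backbone stays ultrametric because the subtree root is placed at
# exactly `height` above the present
graft_tip <- function(backbone, tip_label, subtree, height) {
  if (length(subtree$tip.label) == 1 || is.null(subtree$edge)) {
    backbone$tip.label[backbone$tip.label == tip_label] <- subtree$tip.label[1]
    return(backbone)
  }
  idx <- match(tip_label, backbone$tip.label)
  tmp <- ape::bind.tree(backbone, subtree, where = idx, position = height)
  ape::drop.tip(tmp, tip_label)
}

coalescent_subtree <- function(n, labels) {
  if (n == 1) return(list(tip.label = labels, edge = NULL))
  t <- ape::rcoal(n)
  t$tip.label <- labels
  t
}

#' Simulate the species tree, chronogram and phylogram of a bundle
#'
#' Builds a Yule species tree whose node ages span
#' `[gap_factor * coal_depth / 2, root_spread * gap_factor * coal_depth / 2]`,
#' grafts a Kingman coalescent of individuals (height `coal_depth / 2`)
#' onto every species tip, and a shallow copy tree of clones (height
#' `intragenomic_div / 2`) onto every individual. The resulting chronogram
#' is ultrametric with species monophyletic by construction. The phylogram
#' applies log-normal per-species rate multipliers to every branch of each
#' species clade (stem included), emulating heterogeneous lineage rates.
#'
#' @param cfg A [sim_config()].
#' @return List with `species_tree` (`NULL` when `k_species = 1`),
#'   `chronogram`, `phylogram`, `multipliers` and `clones_per_individual`.
#' @export
simulate_trees <- function(cfg) {
  set.seed(cfg$seed)
  k <- cfg$k_species
  h_within <- cfg$coal_depth / 2
  h_clone <- cfg$intragenomic_div / 2
  g_min <- cfg$gap_factor * cfg$coal_depth / 2

  species_tree <- NULL
  if (k >= 2) {
    species_tree <- ape::rphylo(k, birth = cfg$species_tree_rate, death = 0)
    species_tree$tip.label <- paste0("sp", seq_len(k))
    species_tree <- remap_node_ages(species_tree, g_min,
                                    g_min * cfg$root_spread)
  }

  clone_counts <- list()
  build_species <- function(s) {
    labels_ind <- paste0("sp", s, "_ind", seq_len(cfg$n_individuals))
    clone_trees <- lapply(labels_ind, function(lab) {
      choices <- seq(cfg$clones_range[1], cfg$clones_range[2])
      n_cl <- choices[sample.int(length(choices), 1)]
      clone_counts[[lab]] <<- n_cl
      cl <- coalescent_subtree(n_cl, paste0(lab, "_cl", seq_len(n_cl)))
      if (n_cl >= 2) cl <- scale_to_height(cl, h_clone)
      cl
    })
    names(clone_trees) <- labels_ind
    if (cfg$n_individuals == 1) {
      cl <- clone_trees[[1]]
      if (is.null(cl$edge)) abort("a species must yield at least 2 sequences")
      return(cl)
    }
    floor_age <- max(1.5 * h_clone, 0.1 * h_within)
    ind_tree <- remap_node_ages(coalescent_subtree(cfg$n_individuals,
                                                   labels_ind),
                                floor_age, h_within)
    for (lab in labels_ind) {
      cl <- clone_trees[[lab]]
      if (is.null(cl$edge)) {
        ind_tree$tip.label[ind_tree$tip.label == lab] <- cl$tip.label[1]
      } else {
        ind_tree <- graft_tip(ind_tree, lab, cl, h_clone)
      }
    }
    ind_tree
  }

  if (k == 1) {
    chronogram <- build_species(1)
  } else {
    chronogram <- species_tree
    for (s in seq_len(k)) {
      sub <- build_species(s)
      height <- max(node_ages(sub))
      chronogram <- graft_tip(chronogram, paste0("sp", s), sub, height)
    }
  }

  mult <- if (cfg$rate_sdlog > 0) {
    stats::rlnorm(k, meanlog = -cfg$rate_sdlog^2 / 2, sdlog = cfg$rate_sdlog)
  } else {
    rep(1, k)
  }
  phylogram <- chronogram
  for (s in seq_len(k)) {
    tips <- grep(paste0("^sp", s, "_"), phylogram$tip.label)
    if (length(tips) == 0) tips <- grep(paste0("^sp", s, "$"), phylogram$tip.label)
    if (length(tips) >= 2) {
      mrca <- ape::getMRCA(phylogram, tips)
      clade_nodes <- c(mrca, unlist(phangorn::Descendants(phylogram, mrca, "all")))
    } else {
      clade_nodes <- tips
    }
    sel <- phylogram$edge[, 2] %in% clade_nodes
    phylogram$edge.length[sel] <- phylogram$edge.length[sel] * mult[s]
  }

  list(species_tree = species_tree, chronogram = chronogram,
       phylogram = phylogram, multipliers = mult,
       clones_per_individual = unlist(clone_counts))
}

#' Simulate sequences along a tree under the K80 model
#'
#' Continuous-time K80 substitution (transition bias `kappa`) from a random
#' root sequence; branch lengths are expected substitutions per site. No
#' indels are simulated, so the output is a gap-free alignment.
#'
#' @param tree Phylogram with branch lengths in substitutions/site.
#' @param cfg A [sim_config()]; uses `seq_length`, `kappa` and `seed`
#'   (offset by 1 so tree and sequence draws are independently
#'   reproducible).
#' @return An aligned sequence table (tibble `seq_id`, `bases`,
#'   `length_bp`).
#' @export
simulate_sequences <- function(tree, cfg) {
  set.seed(cfg$seed + 1L)
  sim <- phangorn::simSeq(tree, l = cfg$seq_length,
                          Q = c(1, cfg$kappa, 1, 1, cfg$kappa, 1),
                          bf = rep(0.25, 4), type = "DNA")
  m <- toupper(as.character(sim))
  tibble(seq_id = rownames(m),
         bases = unname(apply(m, 1, paste0, collapse = "")),
         length_bp = cfg$seq_length)
}

#' Degrade a fraction of simulated sequences
#'
#' Emulates the data-quality artifacts seen in archival rDNA submissions:
#' a fraction of sequences truncated (5' columns replaced by gaps, leaving
#' `trunc_length` bp) and a fraction given extra substitutions confined to
#' the first quarter of the alignment columns.
#'
#' @param aln Aligned sequence table.
#' @param cfg A [sim_config()]; uses the `degrade` entry and `seed`
#'   (offset by 2).
#' @return The degraded alignment; affected records are reported in the
#'   `"degraded"` attribute (seq_id, action).
#' @export
degrade_sequences <- function(aln, cfg) {
  set.seed(cfg$seed + 2L)
  deg <- cfg$degrade
  m <- seq_matrix(aln)
  w <- ncol(m)
  actions <- tibble(seq_id = character(0), action = character(0))

  n_short <- round(deg$short_fraction * nrow(aln))
  if (n_short > 0) {
    shorts <- sample(aln$seq_id, n_short)
    cut <- w - deg$trunc_length
    if (cut > 0) m[shorts, seq_len(cut)] <- "-"
    actions <- bind_rows(actions, tibble(seq_id = shorts, action = "short"))
  }
  n_err <- round(deg$five_prime_fraction * nrow(aln))
  if (n_err > 0) {
    noisy <- sample(aln$seq_id, n_err)
    region <- seq_len(floor(w / 4))
    for (sid in noisy) {
      hit <- region[runif(length(region)) < deg$five_prime_error_rate]
      hit <- hit[m[sid, hit] != "-"]  # truncated stretches stay gapped
      if (length(hit) > 0) {
        m[sid, hit] <- vapply(m[sid, hit], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, "")
      }
    }
    actions <- bind_rows(actions, tibble(seq_id = noisy, action = "five_prime_errors"))
  }
  out <- matrix_to_aln(m, aln)
  attr(out, "degraded") <- actions
  out
}

#' Emit a full synthetic bundle with truth labels
#'
#' Runs [simulate_trees()], [simulate_sequences()] and
#' [degrade_sequences()], assembles specimen metadata (degraded records are
#' back-dated to 1996) and the true delimitation, and optionally writes the
#' bundle (FASTA, metadata TSV, two Newick trees, truth TSV) to a
#' directory. Byte-reproducible under a fixed seed.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory.
#' @return List with `alignment`, `meta`, `chronogram`, `phylogram`,
#'   `species_tree`, `truth` (a delimitation) and, when written, `paths`.
#' @export
emit_bundle <- function(cfg, dir = NULL) {
  trees <- simulate_trees(cfg)
  aln <- simulate_sequences(trees$phylogram, cfg)
  aln <- degrade_sequences(aln, cfg)
  degraded <- attr(aln, "degraded")

  species <- sub("_ind.*$", "", aln$seq_id)
  individual <- sub("_cl[0-9]+$", "", aln$seq_id)
  meta <- tibble(
    seq_id = aln$seq_id,
    morphospecies = "Simuloforamina synthetica",
    individual_id = individual,
    clone_id = aln$seq_id,
    type_label = species,
    year = ifelse(aln$seq_id %in% degraded$seq_id, 1996L, 2010L)
  )
  truth <- new_delimitation(tibble(seq_id = aln$seq_id, motu_id = species),
                            provenance = "truth")
  out <- list(alignment = aln, meta = meta, chronogram = trees$chronogram,
              phylogram = trees$phylogram, species_tree = trees$species_tree,
              truth = truth, multipliers = trees$multipliers)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(fasta = file.path(dir, "sequences.fasta"),
                  meta = file.path(dir, "metadata.tsv"),
                  chronogram = file.path(dir, "chronogram.nwk"),
                  phylogram = file.path(dir, "phylogram.nwk"),
                  truth = file.path(dir, "truth.tsv"))
    write_fasta(aln, paths$fasta)
    utils::write.table(meta, paths$meta, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_newick(trees$chronogram, paths$chronogram)
    write_newick(trees$phylogram, paths$phylogram)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}
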