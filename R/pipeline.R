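#' Configuration for a full delimitation run
#'
#' Either a synthetic-data configuration or paths to real inputs (FASTA,
#' metadata TSV, and optionally a phylogram and a chronogram in Newick).
#' When no phylogram is supplied, a neighbor-joining tree built from K80
#' distances stands in for an externally estimated maximum-likelihood
#' phylogram; when no chronogram is supplied, a UPGMA tree stands in for an
#' externally dated chronogram. Both fallbacks are prominently logged.
#'
#' @param sim Optional [sim_config()]; mutually exclusive with `fasta`.
#' @param fasta,meta,phylogram,chronogram Input file paths.
#' @param block Optional 0-based half-open column interval `c(start, end)`
#'   of the homologous analysis block.
#' @param min_coverage Non-gap coverage a record needs inside the block.
#' @param abgd An [abgd_config()].
#' @param gmyc_df Degrees of freedom of the GMYC likelihood-ratio test.
#' @param min_n Minimum distance-class size for conclusive statistics.
#' @param stages Which stages to run, in order, among `"distances"`,
#'   `"abgd"`, `"gmyc"`, `"consensus"`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = NULL, fasta = NULL, meta = NULL,
                       phylogram = NULL, chronogram = NULL, block = NULL,
                       min_coverage = 0.95, abgd = abgd_config(),
                       gmyc_df = 3, min_n = 3,
                       stages = c("distances", "abgd", "gmyc", "consensus")) {
  if (is.null(sim) && is.null(fasta)) {
    abort("run_config needs either a sim config or a FASTA path")
  }
  stopifnot(all(stages %in% c("distances", "abgd", "gmyc", "consensus")))
  structure(list(sim = sim, fasta = fasta, meta = meta,
                 phylogram = phylogram, chronogram = chronogram,
                 block = block, min_coverage = min_coverage, abgd = abgd,
                 gmyc_df = gmyc_df, min_n = min_n, stages = stages),
            class = "run_config")
}

#' Run the whole delimitation pipeline
#'
#' For every morpho-species in the dataset: dereplicate identical
#' sequences, compute K80 and patristic distances, run the ABGD prior scan
#' with clone-consistent plateau selection, fit the single-threshold GMYC
#' model on the chronogram, merge clone-split MOTUs, screen artifact
#' singletons, cross-validate each candidate delimitation against the
#' patristic distance classes, and assemble the method-congruence report
#' and consensus species table. Deterministic for a fixed configuration.
#'
#' @param cfg A [run_config()].
#' @return A `delimitation_report`: list with `per_species` (stage results
#'   per morpho-species), `species_table`, `congruence`, `log` (tibble of
#'   stage messages) and the echoed `config`.
#' @export
run_all <- function(cfg) {
  log <- tibble(stage = character(0), message = character(0))
  note <- function(stage, msg) {
    log <<- bind_rows(log, tibble(stage = stage, message = msg))
  }

  if (!is.null(cfg$sim)) {
    bundle <- emit_bundle(cfg$sim)
    aln <- join_metadata(bundle$alignment, bundle$meta)
    phylogram <- bundle$phylogram
    chronogram <- bundle$chronogram
    truth <- bundle$truth
    note("input", sprintf("synthetic bundle: %d sequences, seed %d",
                          nrow(aln), cfg$sim$seed))
  } else {
    seqs <- read_fasta(cfg$fasta)
    meta_tbl <- utils::read.delim(cfg$meta, sep = "\t",
                                  stringsAsFactors = FALSE)
    aln <- join_metadata(seqs, meta_tbl)
    phylogram <- if (!is.null(cfg$phylogram)) {
      read_newick(cfg$phylogram, known_tips = seqs$seq_id)
    }
    chronogram <- if (!is.null(cfg$chronogram)) {
      read_newick(cfg$chronogram, known_tips = seqs$seq_id)
    }
    truth <- NULL
    note("input", sprintf("%d sequences read from %s", nrow(aln), cfg$fasta))
  }
  if (!is.null(cfg$block)) {
    aln <- extract_block(aln, cfg$block[1], cfg$block[2], cfg$min_coverage)
    dropped <- attr(aln, "dropped")
    note("block", sprintf("block [%d,%d): %d record(s) dropped for coverage",
                          cfg$block[1], cfg$block[2], nrow(dropped)))
  }

  groups <- unique(aln$morphospecies)
  groups <- groups[!is.na(groups)]
  per_species <- list()
  for (sp in groups) {
    sub <- aln[!is.na(aln$morphospecies) & aln$morphospecies == sp, ]
    if (nrow(sub) < 3) {
      note(sp, "fewer than 3 sequences; skipped")
      next
    }
    per_species[[sp]] <- run_one_species(sub, phylogram, chronogram, cfg, note)
  }

  cong <- NULL
  table_rows <- NULL
  if ("consensus" %in% cfg$stages) {
    cong <- purrr::map_dfr(names(per_species), function(sp) {
      r <- per_species[[sp]]
      if (is.null(r$abgd) || is.null(r$gmyc)) return(NULL)
      mutate(congruence(r$abgd, r$gmyc), morphospecies = sp)
    })
    table_rows <- purrr::map_dfr(names(per_species), function(sp) {
      r <- per_species[[sp]]
      if (is.null(r$abgd) || is.null(r$gmyc)) return(NULL)
      build_species_table(literature = r$literature, abgd = r$abgd,
                          gmyc = r$gmyc, verdicts = r$verdicts,
                          meta = aln)
    })
  }

  out <- list(per_species = per_species, species_table = table_rows,
              congruence = cong, truth = truth, log = log, config = cfg)
  class(out) <- "delimitation_report"
  out
}

run_one_species <- function(sub, phylogram, chronogram, cfg, note) {
  sp <- sub$morphospecies[1]
  res <- list()

  derep <- dereplicate(sub)
  reps <- derep$alignment
  note(sp, sprintf("%d sequences, %d unique", nrow(sub), nrow(reps)))
  res$derep_map <- derep$map

  k80 <- k80_matrix(reps)
  res$k80 <- k80

  res$literature <- if (any(!is.na(sub$type_label))) {
    lit <- sub[!is.na(sub$type_label), c("seq_id", "type_label")]
    new_delimitation(tibble(seq_id = lit$seq_id, motu_id = lit$type_label),
                     provenance = "literature")
  }

  sp_phylo <- subset_tree(phylogram, reps$seq_id)
  if (is.null(sp_phylo)) {
    note(sp, "FALLBACK: no phylogram supplied; neighbor-joining tree used for patristic distances")
    sp_phylo <- nj_tree(k80)
  }
  patristic <- patristic_matrix(sp_phylo)
  res$patristic <- patristic

  if ("distances" %in% cfg$stages) {
    res$classes_literature <- classify_distances(patristic, sub,
                                                 res$literature)
    res$gap_literature <- gap_statistics(res$classes_literature)
  }

  if ("abgd" %in% cfg$stages) {
    abgd_reps <- abgd_delimit(k80, sub, cfg$abgd)
    res$abgd_series <- attr(abgd_reps, "series")
    res$abgd <- merge_clone_splits(expand_delimitation(abgd_reps, derep$map),
                                   sub)
    disc <- attr(abgd_reps, "discarded")
    if (!is.null(disc) && nrow(disc) > 0) {
      note(sp, sprintf("ABGD: %d clone-splitting hypothese(s) discarded",
                       nrow(disc)))
    }
  }

  if ("gmyc" %in% cfg$stages) {
    sp_chrono <- subset_tree(chronogram, reps$seq_id)
    if (is.null(sp_chrono)) {
      note(sp, "FALLBACK: no chronogram supplied; UPGMA tree used for GMYC")
      sp_chrono <- upgma_chronogram(k80)
    }
    fit <- fit_single_threshold(sp_chrono, df = cfg$gmyc_df)
    res$gmyc_fit <- fit
    res$gmyc <- merge_clone_splits(
      expand_delimitation(fit$delimitation, derep$map), sub)
    screen <- screen_singletons(res$gmyc, sub, sub)
    res$singleton_flags <- screen$flags
    if (any(screen$flags$suspect)) {
      note(sp, sprintf("%d suspect singleton(s) flagged",
                       sum(screen$flags$suspect)))
    }
  }

  if ("consensus" %in% cfg$stages && !is.null(res$abgd) && !is.null(res$gmyc)) {
    res$verdicts <- list(
      abgd = crossvalidate(res$abgd, patristic, sub, cfg$min_n),
      gmyc = crossvalidate(res$gmyc, patristic, sub, cfg$min_n)
    )
    if (!is.null(res$literature)) {
      res$verdicts$literature <- crossvalidate(res$literature, patristic,
                                               sub, cfg$min_n)
    }
  }
  res
}

subset_tree <- function(tree, tips) {
  if (is.null(tree)) return(NULL)
  keep <- intersect(tree$tip.label, tips)
  if (length(keep) < 3) return(NULL)
  ape::keep.tip(tree, keep)
}

#' @export
print.delimitation_report <- function(x, ...) {
  cat("Delimitation report:", length(x$per_species), "morpho-species\n")
  for (sp in names(x$per_species)) {
    r <- x$per_species[[sp]]
    cat(sprintf("  %s: ABGD %s MOTUs, GMYC %s MOTUs\n", sp,
                if (is.null(r$abgd)) "-" else motu_count(r$abgd),
                if (is.null(r$gmyc)) "-" else motu_count(r$gmyc)))
  }
  if (!is.null(x$species_table)) {
    cat("Species table:\n")
    print(x$species_table)
  }
  invisible(x)
}
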