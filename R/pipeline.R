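write_tsv_report <- function(df, path, comment) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", comment), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  path
}

#' Run the full two-lineage analysis pipeline
#'
#' Orchestrates every stage on a pre-aligned protein FASTA plus matching
#' CDS FASTA and a two-column lineage partition: family/subfamily
#' clustering, back-translation, partial-deletion filtering,
#' parsimony-informative site extraction, lineage site classification
#' (with per-isoform residue numbering for the lineage-fixed sites),
#' nucleotide and amino-acid composition contrasts, per-lineage RSCU,
#' within/between divergence, the codon Z-test of purifying selection,
#' per-site dN/dS categories and Tajima's D. Writes a TSV/JSON report
#' bundle plus a manifest of all parameters; reruns with identical inputs
#' and seed produce byte-identical output. Any stage error is reported
#' with the stage name and partial outputs are removed.
#'
#' @param aligned_fasta Path to the aligned protein FASTA (`-` gaps).
#' @param cds_fasta Path to the matching unaligned CDS FASTA.
#' @param partition Path to the id/lineage TSV, or a [lineage_partition()].
#' @param outdir Output directory (created if needed).
#' @param protein_fasta Optional unaligned protein FASTA used for family
#'   classification; defaults to the ungapped alignment rows.
#' @param coverage Partial-deletion site coverage cut-off (default 0.95).
#' @param family_id,subfamily_id Percent-identity thresholds (40 / 60).
#' @param model Distance model for divergence, `"p"` or `"jc"`.
#' @param correction Nei-Gojobori correction, `"none"` or `"jc"`.
#' @param n_boot Bootstrap replicates (divergence SE and Z-test).
#' @param seed Integer RNG seed recorded in the manifest.
#' @param code A [genetic_code()].
#' @return Invisibly, a list with every stage result and `files` (the
#'   paths written).
#' @export
run_pipeline <- function(aligned_fasta, cds_fasta, partition, outdir,
                         protein_fasta = NULL, coverage = 0.95,
                         family_id = 40, subfamily_id = 60,
                         model = c("p", "jc"),
                         correction = c("none", "jc"),
                         n_boot = 1000L, seed = 1L,
                         code = genetic_code()) {
  model <- match.arg(model)
  correction <- match.arg(correction)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  written <- character(0)
  emit <- function(path) { written <<- c(written, path); path }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  aln <- stage("read_alignment", {
    x <- read_fasta(aligned_fasta, kind = "protein")
    protein_alignment(x)
  })
  cds <- stage("read_cds", read_fasta(cds_fasta, kind = "cds"))
  part <- stage("read_partition", {
    if (inherits(partition, "lineage_partition")) partition
    else read_partition(partition)
  })
  stage("check_partition", check_partition_covers(part, rownames(aln$matrix)))
  lin <- attr(part, "lineages")

  fam <- stage("family_classification", {
    prot <- if (is.null(protein_fasta)) {
      setNames(ungap(alignment_strings(aln)), rownames(aln$matrix))
    } else read_fasta(protein_fasta, kind = "protein")
    assign_families(prot, agnc_thresholds(family_id, subfamily_id))
  })
  stage("write_families", {
    write_tsv_report(fam$assignment, emit(file.path(outdir, "families.tsv")),
                     "family/subfamily clusters from pairwise identity thresholds")
    jsonlite::write_json(family_frequencies(fam),
                         emit(file.path(outdir, "family_frequencies.json")),
                         dataframe = "rows", digits = NA)
  })

  codon_aln <- stage("back_translate", back_translate(aln, cds, code))
  codon_kept <- stage("partial_deletion", partial_deletion(codon_aln, coverage))
  prot_kept <- stage("partial_deletion_protein",
                     partial_deletion(aln, coverage))

  sites <- stage("site_classification",
                 classify_lineage_sites(prot_kept, part, sites = "informative"))
  stage("write_sites", write_tsv_report(
    as.data.frame(sites), emit(file.path(outdir, "sites.tsv")),
    "lineage polymorphism classification of parsimony-informative protein columns"))

  site_numbers <- stage("site_numbering", {
    fixed_rows <- sites[grepl("strictly_dimorphic|fixed_in", sites$category), ]
    if (nrow(fixed_rows) == 0L) {
      data.frame(column = integer(0))
    } else {
      ids <- rownames(prot_kept$matrix)
      num <- lapply(fixed_rows$column, function(colorig) {
        j <- match(colorig, prot_kept$columns)
        vapply(ids, function(id) {
          if (prot_kept$matrix[id, j] == "-") return(NA_character_)
          paste0(prot_kept$matrix[id, j],
                 column_to_residue_number(prot_kept, id, j))
        }, character(1))
      })
      cbind(data.frame(column = fixed_rows$column,
                       category = fixed_rows$category),
            as.data.frame(do.call(rbind, num)))
    }
  })
  stage("write_site_numbers", write_tsv_report(
    site_numbers, emit(file.path(outdir, "site_numbers.tsv")),
    "per-isoform residue numbers at lineage-fixed sites"))

  # composition defaults to the informative-site universe; an alignment
  # without informative columns falls back to all sites
  comp_nt <- stage("nucleotide_composition", tryCatch(
    codon_position_composition(codon_kept, part),
    error = function(e)
      codon_position_composition(codon_kept, part, site_filter = "all")))
  comp_aa <- stage("amino_acid_composition", tryCatch(
    amino_acid_composition(prot_kept, part),
    error = function(e)
      amino_acid_composition(prot_kept, part, site_filter = "all")))
  stage("write_composition", {
    write_tsv_report(as.data.frame(comp_nt),
                     emit(file.path(outdir, "composition_nt.tsv")),
                     "nucleotide frequencies by codon position (informative sites), group mean +/- SE, pooled t")
    write_tsv_report(as.data.frame(comp_aa),
                     emit(file.path(outdir, "composition_aa.tsv")),
                     "amino-acid frequencies (informative sites), group mean +/- SE, pooled t")
  })

  rscu_tabs <- stage("rscu", {
    out <- NULL
    for (g in lin) {
      tab <- rscu(cds[names(part)[part == g]], code)
      names(tab)[names(tab) == "count"] <- paste0("count_", g)
      names(tab)[names(tab) == "rscu"] <- paste0("rscu_", g)
      tab[[paste0("defined_", g)]] <- tab$defined
      tab$defined <- NULL
      out <- if (is.null(out)) tab else
        merge(out, tab, by = c("codon", "amino_acid"), sort = TRUE)
    }
    out[order(out$amino_acid, out$codon), ]
  })
  stage("write_rscu", write_tsv_report(
    rscu_tabs, emit(file.path(outdir, "rscu.tsv")),
    "relative synonymous codon usage per lineage"))

  div <- stage("group_divergence",
               group_divergence(codon_kept, part, model = model,
                                n_boot = n_boot, seed = seed))
  zt <- stage("codon_z_test",
              codon_z_test(codon_kept, part, alternative = "purifying",
                           n_boot = n_boot, seed = seed,
                           correction = correction, code = code))
  psd <- stage("per_site_dnds", per_site_dnds(codon_kept, code))
  taj <- stage("tajimas_d", tajimas_d(codon_kept))

  stage("write_selection", {
    jsonlite::write_json(list(
      divergence = div,
      z_test = zt[c("Z", "p", "mean_dS", "mean_dN", "n_pairs", "n_boot",
                    "alternative", "flags")],
      per_site_counts = as.list(psd$counts),
      tajima = taj[c("n", "L", "S", "k", "pi", "theta", "D", "flags")]),
      emit(file.path(outdir, "selection.json")),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, force = TRUE)
    write_tsv_report(psd$table, emit(file.path(outdir, "per_site_dnds.tsv")),
                     "per-codon-column Nei-Gojobori counts and dN/dS category")
  })

  manifest <- list(
    package = "lineagediv",
    version = as.character(utils::packageVersion("lineagediv")),
    seed = seed, coverage = coverage,
    thresholds = list(family = family_id, subfamily = subfamily_id),
    distance_model = model, ng_correction = correction, n_boot = n_boot,
    genetic_code = code$id,
    n_sequences = n_sequences(aln), lineages = as.list(table(part)),
    n_codon_columns_total = length(codon_aln$columns),
    n_codon_columns_kept = length(codon_kept$columns),
    kept_codon_columns = codon_kept$columns)
  stage("write_manifest", jsonlite::write_json(
    manifest, emit(file.path(outdir, "manifest.json")),
    auto_unbox = TRUE, digits = NA))

  invisible(list(alignment = aln, codon_alignment = codon_kept,
                 partition = part, families = fam, sites = sites,
                 site_numbers = site_numbers, composition_nt = comp_nt,
                 composition_aa = comp_aa, rscu = rscu_tabs,
                 divergence = div, z_test = zt, per_site = psd,
                 tajima = taj, manifest = manifest, files = written))
}
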