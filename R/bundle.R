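# One-call synthetic bundle writer: emits every input format the pipeline
# consumes, for CLI use and end-to-end I/O testing.

#' Write a complete synthetic input bundle to disk
#'
#' Generates `n_cell_types` synthetic cell types plus shared gene models,
#' conservation, expression, and SNPs, and writes them in the external
#' formats the pipeline reads: chrom sizes TSV, per-cell-type annotation
#' BEDs, per-(cell type, mark) normalized bedGraphs with a manifest TSV,
#' a GTF, an expression TSV, a SNP BED, and a JSON file of the generative
#' truth. Byte-reproducible given (arguments, seed).
#'
#' @param out_dir output directory (created if missing).
#' @param seed master RNG seed; per-component seeds are derived from it.
#' @param layout a `GenomeLayout`.
#' @param n_cell_types number of simulated cell types.
#' @param n_genes gene count.
#' @param n_snps SNP count.
#' @param snp_enrichment score enrichment of SNP placement.
#' @param signatures signature table.
#' @return invisibly, a named list of written paths.
#' @export
write_synth_bundle <- function(out_dir, seed = 1,
                               layout = default_genome_layout(),
                               n_cell_types = 3, n_genes = 60,
                               n_snps = 2000, snp_enrichment = 2,
                               signatures = default_signature_table()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  paths$chrom_sizes <- file.path(out_dir, "genome.chrom.sizes")
  write_chrom_sizes(layout, paths$chrom_sizes)
  genes <- simulate_genes(layout, n_genes = n_genes, seed = seed)
  paths$genes <- file.path(out_dir, "genes.gtf")
  write_genes_gtf(genes, paths$genes)
  genome <- simulate_genome(layout, signatures, genes = genes, seed = seed)
  man <- list(); anns <- list(); caas <- list(); terms <- list()
  truths <- list()
  for (i in seq_len(n_cell_types)) {
    ct <- sprintf("synth%02d", i)
    sim <- simulate_cell_type(genome, seed = seed * 1000 + i,
                              cell_type = ct)
    tm <- sim$truth$state_term
    bed <- file.path(out_dir, paste0(ct, ".annotation.bed"))
    write_annotation_bed(sim$annotation, bed, terms = tm)
    paths[[paste0("annotation_", ct)]] <- bed
    for (m in names(sim$tracks)) {
      bg <- file.path(out_dir, paste0(ct, ".", m, ".bedGraph"))
      write_track_bedgraph(sim$tracks[[m]], bg)
      man[[length(man) + 1]] <- data.frame(
        cell_type = ct, assay_type = m, path = basename(bg),
        format = "bedGraph", stringsAsFactors = FALSE)
    }
    truths[[ct]] <- sim$truth
    anns[[i]] <- sim$annotation
    terms[[i]] <- tm
  }
  paths$manifest <- file.path(out_dir, "tracks.tsv")
  utils::write.table(do.call(rbind, man), paths$manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cons <- simulate_conservation(genome, seed = seed + 7)
  paths$phylop <- file.path(out_dir, "phylop.bedGraph")
  write_track_bedgraph(cons, paths$phylop)
  expr <- simulate_expression(truths, genes, seed = seed + 11)
  paths$expression <- file.path(out_dir, "expression.tsv")
  utils::write.table(data.frame(gene_id = rownames(expr), expr,
                                check.names = FALSE),
                     paths$expression, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (i in seq_len(n_cell_types))
    caas[[i]] <- compute_state_caas(anns[[i]], cons)
  scores <- compute_position_scores(anns, caas, terms)
  snps <- simulate_snps(scores, enrichment = snp_enrichment,
                        n_snps = n_snps, seed = seed + 13)
  paths$snps <- file.path(out_dir, "snps.bed")
  write_snps_bed(snps, paths$snps)
  truth_json <- file.path(out_dir, "truth.json")
  tj <- lapply(truths, function(tr)
    list(state_term = as.list(tr$state_term), seed = tr$seed,
         config = tr$config))
  writeLines(.to_json(list(seed = seed, cell_types = tj)), truth_json)
  paths$truth <- truth_json
  invisible(paths)
}

# minimal deterministic JSON serializer (scalars, named lists, vectors)
.to_json <- function(x) {
  if (is.list(x)) {
    if (is.null(names(x)))
      paste0("[", paste(vapply(x, .to_json, ""), collapse = ","), "]")
    else
      paste0("{", paste(paste0('"', names(x), '":',
                               vapply(x, .to_json, "")), collapse = ","),
             "}")
  } else if (length(x) > 1) {
    paste0("[", paste(vapply(x, .to_json, ""), collapse = ","), "]")
  } else if (is.character(x)) {
    paste0('"', gsub('"', '\\\\"', x), '"')
  } else if (is.logical(x)) {
    if (x) "true" else "false"
  } else {
    format(x, digits = 15, scientific = FALSE, trim = TRUE)
  }
}
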