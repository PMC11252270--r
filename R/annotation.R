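#' Read a gene annotation with TSS and activity flags
#'
#' Reads gene features from a GFF3 file and reduces each gene to its
#' transcription start site: a width-1 interval at the 5' end of the gene
#' (start on `+`, end on `-`; unstranded genes use the start). The
#' transcriptionally-active flag is taken from an `active` attribute when
#' present (`true`/`false`, case-insensitive, also `1`/`0`/`yes`/`no`),
#' otherwise all genes are marked active. Activity is an input here — see
#' [set_active_genes()] to derive it from an expression table.
#'
#' @param path GFF3 file path.
#' @param feature_type Feature type(s) to keep (default `"gene"`).
#' @return A width-1 `GRanges` (one per gene, at the TSS) with metadata
#'   columns `gene_id`, `gene_name`, `active`. `gene_id` is unique.
#' @export
read_gene_annotation <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$type)) gr <- gr[as.character(mc$type) %in% feature_type]
  if (!length(gr)) stop("no '", feature_type, "' features in ", path)
  mc <- S4Vectors::mcols(gr)
  gene_id <- if (!is.null(mc$ID)) as.character(mc$ID) else
    if (!is.null(mc$gene_id)) as.character(mc$gene_id) else
      stop("GFF3 gene features lack ID/gene_id attributes: ", path)
  gene_name <- if (!is.null(mc$Name)) as.character(mc$Name) else gene_id
  active <- if (!is.null(mc$active)) {
    tolower(as.character(mc$active)) %in% c("true", "1", "yes")
  } else rep(TRUE, length(gr))
  gene_annotation(
    gene_id = gene_id, gene_name = gene_name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    tss = ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                 GenomicRanges::end(gr), GenomicRanges::start(gr)) - 1L,
    strand = as.character(GenomicRanges::strand(gr)),
    active = active
  )
}

#' Construct a gene annotation from vectors
#'
#' @param gene_id Unique gene identifiers.
#' @param chrom Chromosome per gene.
#' @param tss 0-based TSS position per gene.
#' @param gene_name Gene symbols (defaults to `gene_id`).
#' @param strand Strand per gene (`+`, `-` or `.`).
#' @param active Logical: transcriptionally active.
#' @return A width-1 `GRanges` with metadata `gene_id`, `gene_name`, `active`.
#' @export
gene_annotation <- function(gene_id, chrom, tss, gene_name = gene_id,
                            strand = ".", active = TRUE) {
  if (anyDuplicated(gene_id)) stop("gene_id must be unique")
  strand[strand == "*"] <- "."
  gr <- genomic_intervals(chrom, tss, tss + 1L, strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = as.character(gene_id), gene_name = as.character(gene_name),
    active = rep_len(as.logical(active), length(gr))
  )
  gr
}

#' Set active flags from an expression table
#'
#' Marks a gene transcriptionally active when its expression meets a
#' threshold. The activity definition is deliberately an input to the
#' super-enhancer gene-assignment step, not something computed inside it.
#'
#' @param genes Annotation from [gene_annotation()]/[read_gene_annotation()].
#' @param expression Named numeric vector or two-column data.frame
#'   (gene_id, expression).
#' @param threshold Minimum expression (inclusive) to be called active.
#'   Genes absent from `expression` become inactive.
#' @return The annotation with updated `active` flags.
#' @export
set_active_genes <- function(genes, expression, threshold) {
  if (is.data.frame(expression)) {
    expression <- stats::setNames(as.numeric(expression[[2]]),
                                  as.character(expression[[1]]))
  }
  e <- expression[S4Vectors::mcols(genes)$gene_id]
  S4Vectors::mcols(genes)$active <- unname(!is.na(e) & e >= threshold)
  genes
}

#' Write a gene annotation as GFF3
#'
#' Emits one `gene` feature per entry, spanning `gene_start`..`gene_end`
#' when provided (otherwise the width-1 TSS itself), with `ID`, `Name` and
#' `active` attributes that [read_gene_annotation()] round-trips.
#'
#' @param genes Annotation `GRanges` (TSS representation).
#' @param path Output path.
#' @param body Optional `GRanges` of gene bodies, parallel to `genes`.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path, body = NULL) {
  gr <- if (is.null(body)) genes else {
    stopifnot(length(body) == length(genes))
    S4Vectors::mcols(body) <- S4Vectors::mcols(genes)
    body
  }
  mc <- S4Vectors::mcols(gr)
  out <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(gr), IRanges::ranges(gr),
    strand = GenomicRanges::strand(gr)
  )
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    source = "secanalyze", type = "gene",
    ID = mc$gene_id, Name = mc$gene_name,
    active = tolower(as.character(mc$active))
  )
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}
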