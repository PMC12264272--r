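#' Construct a gene signature
#'
#' A gene signature is a named gene set in which each gene carries a
#' direction: `up_genes` move up with risk (they are reflected before being
#' combined with the protective arm), `down_genes` move down with risk and
#' are used as-is.
#'
#' @param name Signature name.
#' @param up_genes Character vector of risk-direction gene symbols.
#' @param down_genes Character vector of protective-direction gene symbols.
#' @param provenance Free-text citation / origin string.
#'
#' @return An object of class `gene_signature`.
#' @export
#'
#' @examples
#' gene_signature("RESIST-M1", up_genes = c("SERPINE1", "SMARCD3"))
gene_signature <- function(name, up_genes = character(), down_genes = character(),
                           provenance = "") {
  up_genes <- as.character(up_genes)
  down_genes <- as.character(down_genes)
  if (length(up_genes) + length(down_genes) == 0L) {
    abort("A gene signature needs at least one gene.")
  }
  overlap <- intersect(up_genes, down_genes)
  if (length(overlap) > 0) {
    abort(sprintf("Genes cannot be both up and down: %s",
                  paste(overlap, collapse = ", ")))
  }
  structure(
    list(name = name, up_genes = up_genes, down_genes = down_genes,
         provenance = provenance),
    class = "gene_signature"
  )
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("<gene_signature> ", x$name, "\n", sep = "")
  if (length(x$up_genes)) cat("  up:  ", paste(x$up_genes, collapse = ", "), "\n")
  if (length(x$down_genes)) cat("  down:", paste(x$down_genes, collapse = ", "), "\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

signature_genes <- function(sig) c(sig$up_genes, sig$down_genes)

#' Built-in signature registry
#'
#' Returns the signatures analysed by this package: the two arms of the
#' nine-gene RESIST-M signature (RESIST-M1: SERPINE1, SMARCD3 up with
#' oxaliplatin resistance; RESIST-M2: seven cholesterol-biosynthesis genes
#' down), their union `RESIST-M`, and four published comparators — the Yin
#' and Lin oxaliplatin-resistance signatures, the seven-gene subset of the
#' colon-cancer recurrence score (`RCC7`, stromal genes plus GADD45B up and
#' cell-cycle genes down), and the four-gene recombination proficiency
#' score (`RPS`).
#'
#' @return Named list of [gene_signature] objects.
#' @export
#'
#' @examples
#' names(builtin_signatures())
#' builtin_signatures()[["RESIST-M"]]
builtin_signatures <- function() {
  m1_up <- c("SERPINE1", "SMARCD3")
  m2_dn <- c("SC5D", "FDPS", "MVD", "HMGCS1", "HMGCR", "CYP51A1", "ACAT2")
  sigs <- list(
    gene_signature("RESIST-M1", up_genes = m1_up,
                   provenance = "RESIST-M risk arm (coagulation / SWI-SNF)"),
    gene_signature("RESIST-M2", down_genes = m2_dn,
                   provenance = "RESIST-M protective arm (cholesterol biosynthesis)"),
    gene_signature("RESIST-M", up_genes = m1_up, down_genes = m2_dn,
                   provenance = "Combined nine-gene RESIST-M signature"),
    gene_signature("Yin", up_genes = c("P4HA1", "ATF6", "PHLDB3", "IBTK", "COPE"),
                   provenance = "Yin et al. oxaliplatin-resistance signature"),
    gene_signature("Lin", up_genes = c("ALCAM", "CD22", "CASP1", "CISH"),
                   provenance = "Lin et al. oxaliplatin-resistance signature"),
    gene_signature("RCC7",
                   up_genes = c("INHBA", "BGN", "FAP", "GADD45B"),
                   down_genes = c("MKI67", "MYC", "MYBL2"),
                   provenance = "Colon-cancer recurrence score, 7 of 12 genes"),
    gene_signature("RPS", up_genes = c("RIF1", "XRCC5", "PARPBP", "RAD51"),
                   provenance = "Recombination proficiency score (DNA repair)")
  )
  setNames(sigs, vapply(sigs, `[[`, character(1), "name"))
}
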