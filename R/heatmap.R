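#' Assemble the z-scored, annotation-ordered signature heatmap table
#'
#' Builds the long-format table behind the annotated signature heatmap:
#' gene rows are grouped into fixed signature blocks (RESIST-M, Lin, Yin,
#' RCC7, RPS, top to bottom), each row is z-scored across samples
#' ([zscore_rows]), and sample columns are ordered by CMS label, then iCMS,
#' then fibrosis status, then the combined reflected-median RESIST-M score
#' (ascending, so the highest-risk pattern sits at the left edge of its
#' annotation stratum).
#'
#' @param expr Expression table.
#' @param clinical Clinical tibble with `sample_id`, `cms`, `icms`, `msi`,
#'   `fibrosis` annotations (survival columns not required).
#' @param registry Named list of [gene_signature]s; default
#'   [builtin_signatures()]. Blocks are taken in the order RESIST-M, Lin,
#'   Yin, RCC7, RPS when present.
#' @param scores Optional precomputed combined score ([score_signature]
#'   output) used as the final sort key; computed from the RESIST-M
#'   signature when `NULL`.
#' @param cms_order Factor order for CMS labels.
#'
#' @return A `heatmap_table`: long tibble with columns `gene`,
#'   `signature_block`, `sample_id`, `zscore`, the annotation columns, and
#'   `status` (median-split on the combined score); sample order is stored
#'   in the `sample_order` attribute. Supports [autoplot()].
#' @export
build_heatmap_table <- function(expr, clinical, registry = builtin_signatures(),
                                scores = NULL,
                                cms_order = c("CMS1", "CMS2", "CMS3", "CMS4")) {
  validate_clinical(clinical, require_survival = FALSE)
  check_matched_ids(expr, clinical)
  block_order <- intersect(c("RESIST-M", "Lin", "Yin", "RCC7", "RPS"),
                           names(registry))
  if (length(block_order) == 0L) abort("Registry has no known signature blocks.")

  if (is.null(scores)) {
    scores <- score_signature(expr, registry[["RESIST-M"]],
                              method = "reflected_median")
  }
  status <- assign_status(scores)

  blocks <- dplyr::bind_rows(lapply(block_order, function(b) {
    genes <- intersect(signature_genes(registry[[b]]), expr$gene)
    tibble::tibble(gene = genes, signature_block = b)
  }))
  blocks <- dplyr::distinct(blocks, .data$gene, .keep_all = TRUE)
  sub <- dplyr::left_join(blocks["gene"], expr, by = "gene")
  z <- zscore_rows(sub)

  ann <- dplyr::left_join(
    tibble::tibble(sample_id = expr_sample_ids(expr)),
    dplyr::select(clinical, dplyr::any_of(c("sample_id", "cms", "icms",
                                            "msi", "fibrosis"))),
    by = "sample_id")
  ann <- dplyr::left_join(ann, dplyr::select(status, "sample_id", "score", "status"),
                          by = "sample_id")
  ann$cms <- factor(ann$cms, levels = cms_order)
  ord <- order(ann$cms, ann$icms, ann$fibrosis, ann$score)
  sample_order <- ann$sample_id[ord]

  long <- tidyr::pivot_longer(z, -"gene", names_to = "sample_id",
                              values_to = "zscore")
  long <- dplyr::left_join(long, blocks, by = "gene")
  long <- dplyr::left_join(long, ann, by = "sample_id")
  long <- dplyr::mutate(
    long,
    sample_id = factor(.data$sample_id, levels = sample_order),
    gene = factor(.data$gene, levels = rev(blocks$gene)),
    signature_block = factor(.data$signature_block, levels = block_order)
  ) |>
    dplyr::arrange(.data$signature_block, .data$gene, .data$sample_id)

  structure(long, class = c("heatmap_table", class(long)),
            sample_order = sample_order, block_order = block_order)
}

#' Heatmap of a signature heatmap table
#'
#' @param object A `heatmap_table` from [build_heatmap_table].
#' @param ... Unused.
#' @return A ggplot tile heatmap faceted by signature block.
#' @export
autoplot.heatmap_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$sample_id, .data$gene,
                                       fill = .data$zscore)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(signature_block ~ cms, scales = "free", space = "free") +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-3, 3),
                                  oob = scales_squish) +
    ggplot2::labs(x = NULL, y = NULL, fill = "z-score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

# clamp to limits without dragging in the scales package
scales_squish <- function(x, range = c(-3, 3)) {
  pmin(pmax(x, range[1]), range[2])
}
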