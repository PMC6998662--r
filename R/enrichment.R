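#' Select the gene set for pathway analysis from DE results
#'
#' Functional predictions exist only for mRNAs (the fragment's own gene) and
#' for miRNAs/isomiRs (predicted targets); all other circulating RNA classes
#' contribute nothing. The returned set is the deduplicated union of (i)
#' gene ids of DE RNAs of class `mRNA` and (ii) predicted targets with
#' score strictly greater than `score_cutoff` of DE RNAs of class `miRNA`
#' or `isomiR`. isomiRs are mapped to their parent miRNA's target list via
#' `isomir_map`.
#'
#' @param de A data frame of differentially expressed RNAs with columns
#'   `rna_id` and `rna_class` (e.g. the `de` entry of a window summary, or
#'   a filtered `de_results`).
#' @param targets Target-prediction table: `mirna_id`, `gene_id`, `score`
#'   (0-100).
#' @param score_cutoff Minimum prediction score, strict inequality
#'   (default 60).
#' @param isomir_map Optional tibble `isomir_id`, `mirna_id` mapping isomiRs
#'   to parent miRNAs.
#' @param gene_map Optional tibble `rna_id`, `gene_id` mapping mRNA features
#'   to gene ids; by default the mRNA feature id is its gene id.
#' @return Sorted character vector of unique gene ids (possibly empty).
#' @export
select_genes <- function(de, targets, score_cutoff = 60, isomir_map = NULL,
                         gene_map = NULL) {
  if (any(targets$score < 0 | targets$score > 100)) {
    abort("target scores must lie in [0, 100]")
  }
  if (nrow(de) == 0) return(character())
  mrna_ids <- de$rna_id[de$rna_class == "mRNA"]
  genes_mrna <- if (is.null(gene_map)) {
    mrna_ids
  } else {
    gene_map$gene_id[match(mrna_ids, gene_map$rna_id)]
  }
  mirna_ids <- de$rna_id[de$rna_class == "miRNA"]
  isomir_ids <- de$rna_id[de$rna_class == "isomiR"]
  if (length(isomir_ids) && !is.null(isomir_map)) {
    parents <- isomir_map$mirna_id[match(isomir_ids, isomir_map$isomir_id)]
    mirna_ids <- c(mirna_ids, parents[!is.na(parents)])
  }
  hits <- targets$mirna_id %in% mirna_ids & targets$score > score_cutoff
  sort(unique(c(genes_mrna[!is.na(genes_mrna)], targets$gene_id[hits])))
}

#' Hypergeometric pathway over-representation test
#'
#' For each pathway, the p-value is the upper tail `P(X >= overlap)` of a
#' hypergeometric draw of `|gene_set|` genes from the universe containing
#' `|pathway (intersect) universe|` pathway members; Benjamini-Hochberg
#' adjustment is applied across pathways.
#'
#' @param gene_set Character vector of selected genes (must be a subset of
#'   the universe).
#' @param pathways Annotation tibble with columns `pathway_id`, `gene_id`
#'   (and optionally `pathway_name`).
#' @param universe Gene universe; defaults to all genes in `pathways`.
#' @return A tibble (one row per pathway, ordered by p): `pathway_id`,
#'   `pathway_name` (if present), `pathway_size` (within the universe),
#'   `overlap`, `p`, `padj`.
#' @examples
#' ann <- tibble::tibble(pathway_id = "P1", gene_id = paste0("g", 1:5))
#' pathway_test(paste0("g", 1:3), ann, universe = paste0("g", 1:20))
#' @export
pathway_test <- function(gene_set, pathways, universe = NULL) {
  if (is.null(universe)) universe <- unique(pathways$gene_id)
  universe <- unique(universe)
  outside <- setdiff(gene_set, universe)
  if (length(outside)) {
    abort(paste0("gene(s) outside the universe: ",
                 paste(head(outside, 10), collapse = ", ")))
  }
  gene_set <- unique(gene_set)
  n_univ <- length(universe)
  n_sel <- length(gene_set)
  by_pw <- split(pathways$gene_id, pathways$pathway_id)
  names_tbl <- if ("pathway_name" %in% names(pathways)) {
    unique(pathways[c("pathway_id", "pathway_name")])
  } else NULL
  rows <- lapply(names(by_pw), function(pw) {
    members <- intersect(unique(by_pw[[pw]]), universe)
    k <- length(members)
    if (k == 0) abort(paste0("pathway has no genes in the universe: ", pw))
    ov <- length(intersect(members, gene_set))
    p <- phyper(ov - 1, k, n_univ - k, n_sel, lower.tail = FALSE)
    tibble::tibble(pathway_id = pw, pathway_size = k, overlap = ov, p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$padj <- adjust_bh(out$p)
  if (!is.null(names_tbl)) {
    out <- dplyr::left_join(out, names_tbl, by = "pathway_id")
    out <- out[c("pathway_id", "pathway_name", "pathway_size", "overlap",
                 "p", "padj")]
  }
  dplyr::arrange(out, .data$p, .data$pathway_id)
}

#' Simulate a toy pathway/target annotation
#'
#' Builds a small synthetic stand-in for real pathway and target-prediction
#' databases: `n_pathways` pathways drawing genes from a universe of
#' `n_genes`, a miRNA-to-target table with prediction scores uniform on
#' [0, 100], and an isomiR-to-parent-miRNA map. Used by the examples and
#' test harnesses; real annotation TSVs can be supplied in the same layout.
#'
#' @param n_genes Universe size.
#' @param n_pathways Number of pathways.
#' @param n_mirnas Number of miRNAs with target predictions.
#' @param n_isomirs Number of isomiRs, each mapped to a parent miRNA.
#' @param seed Integer seed.
#' @return A list: `pathways`, `targets`, `isomir_map` tibbles.
#' @details A pre-generated copy ships with the package:
#'   `system.file("extdata", "synthetic_pathways.tsv", package = "serotraj")`
#'   (plus `synthetic_mirna_targets.tsv` and `synthetic_isomir_map.tsv`),
#'   all fully synthetic.
#' @export
simulate_annotation <- function(n_genes = 500, n_pathways = 30, n_mirnas = 40,
                                n_isomirs = 20, seed = 1L) {
  withr::with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    pathways <- dplyr::bind_rows(lapply(seq_len(n_pathways), function(i) {
      size <- sample(8:40, 1)
      tibble::tibble(
        pathway_id = sprintf("pw%02d", i),
        pathway_name = sprintf("Synthetic pathway %02d", i),
        gene_id = sample(genes, size)
      )
    }))
    targets <- dplyr::bind_rows(lapply(seq_len(n_mirnas), function(i) {
      n_t <- sample(10:40, 1)
      tibble::tibble(
        mirna_id = sprintf("mir%03d", i),
        gene_id = sample(genes, n_t),
        score = round(runif(n_t, 0, 100), 1)
      )
    }))
    isomir_map <- tibble::tibble(
      isomir_id = sprintf("iso%03d", seq_len(n_isomirs)),
      mirna_id = sprintf("mir%03d", sample(n_mirnas, n_isomirs, replace = TRUE))
    )
    list(pathways = pathways, targets = targets, isomir_map = isomir_map)
  })
}
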