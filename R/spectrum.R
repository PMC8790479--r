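# Fold an HGVS descriptor for matching: strip whitespace, lower-case the
# leading "c." prefix.  No further normalization: descriptors are otherwise
# carried verbatim.
fold_hgvs <- function(x) {
  x <- gsub("[[:space:]]+", "", x)
  sub("^C\\.", "c.", x)
}

#' Read genotype records from a tab-separated table
#'
#' Expects columns `case_id`, `gene` and up to three allele slots
#' (`allele1_c`, `allele1_p`, `allele2_c`, `allele2_p`, `allele3_c`,
#' `allele3_p`); `-` or empty cells mark absent alleles.  HGVS strings are
#' kept verbatim apart from whitespace/case folding of the `c.` prefix.
#'
#' @param path path to the TSV; defaults to the shipped confirmed-case
#'   genotypes.
#' @return data frame, one row per detected allele: `case_id`, `gene`,
#'   `slot`, `variant_c`, `variant_p`.
#' @export
read_genotypes <- function(path = NULL) {
  path <- path %||% nbs_extdata("case_genotypes.tsv")
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = TRUE)
  stopifnot(all(c("case_id", "gene") %in% names(raw)))
  out <- list()
  for (slot in 1:3) {
    c_col <- paste0("allele", slot, "_c")
    p_col <- paste0("allele", slot, "_p")
    if (!c_col %in% names(raw)) next
    vc <- fold_hgvs(raw[[c_col]])
    present <- !is.na(vc) & nzchar(vc) & vc != "-"
    if (!any(present)) next
    vp <- if (p_col %in% names(raw)) raw[[p_col]][present] else NA_character_
    vp[vp == "-" | !nzchar(vp)] <- NA_character_
    out[[length(out) + 1L]] <- data.frame(
      case_id = raw$case_id[present], gene = raw$gene[present],
      slot = slot, variant_c = vc[present], variant_p = vp,
      stringsAsFactors = FALSE)
  }
  alleles <- do.call(rbind, out)
  alleles <- alleles[order(match(alleles$case_id, raw$case_id), alleles$slot), ]
  rownames(alleles) <- NULL
  alleles
}

#' Count detected variant alleles by gene
#'
#' Each detected allele contributes one count; absent alleles contribute
#' nothing, and a record with no detected alleles contributes nothing.
#' Counts are grouped by `(gene, nucleotide variant)`; the first observed
#' protein descriptor is carried as annotation.
#'
#' @param alleles data frame as returned by [read_genotypes()] (columns
#'   `gene`, `variant_c`, optionally `variant_p`).
#' @return data frame `gene`, `variant_c`, `variant_p`, `count`, ordered by
#'   gene and decreasing count.
#' @export
count_alleles <- function(alleles) {
  stopifnot(is.data.frame(alleles),
            all(c("gene", "variant_c") %in% names(alleles)))
  if (!nrow(alleles)) {
    return(data.frame(gene = character(), variant_c = character(),
                      variant_p = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  vc <- fold_hgvs(alleles$variant_c)
  key <- paste(alleles$gene, vc, sep = "\r")
  tab <- table(key)
  first <- !duplicated(key)
  ann <- alleles[first, , drop = FALSE]
  ann_key <- key[first]
  out <- data.frame(
    gene = ann$gene[match(names(tab), ann_key)],
    variant_c = vc[first][match(names(tab), ann_key)],
    variant_p = if ("variant_p" %in% names(alleles))
      ann$variant_p[match(names(tab), ann_key)] else NA_character_,
    count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene, -out$count, out$variant_c), ]
  rownames(out) <- NULL
  out
}

#' Relative allele frequencies of the mutation spectrum
#'
#' Computes, for every `(gene, variant)`, its allele count, its relative
#' frequency within its gene (or within its disease group, when a gene ->
#' group map pools genes such as PAH and PTS into hyperphenylalaninemia),
#' and its share of all detected alleles; plus per-gene and per-group
#' roll-ups.  All percentages are reported to 2 dp, half-up.
#'
#' @param counts data frame with columns `gene`, `variant_c`, `count`
#'   (e.g. from [count_alleles()] or [nbs_variant_counts()]).
#' @param group_map named list group -> character vector of genes (see
#'   [nbs_group_map()]); genes not mentioned form their own group.
#' @return an object of class `nbs_spectrum`: list with `variants`, `genes`,
#'   `groups` data frames and `grand_total`.
#' @examples
#' spec <- relative_frequencies(nbs_variant_counts(), nbs_group_map())
#' head(spec$variants)
#' @export
relative_frequencies <- function(counts, group_map = NULL) {
  stopifnot(is.data.frame(counts),
            all(c("gene", "variant_c", "count") %in% names(counts)))
  if (!nrow(counts) || sum(counts$count) < 1) {
    stop("cannot compute relative frequencies from an empty allele table")
  }
  gene_group <- stats::setNames(unique(counts$gene), unique(counts$gene))
  if (!is.null(group_map)) {
    for (grp in names(group_map)) {
      gene_group[group_map[[grp]][group_map[[grp]] %in% names(gene_group)]] <- grp
    }
  }
  counts$group <- unname(gene_group[counts$gene])
  grand <- sum(counts$count)
  group_tot <- tapply(counts$count, counts$group, sum)
  gene_tot <- tapply(counts$count, counts$gene, sum)

  variants <- counts
  variants$within_percent <- round_half_up(
    100 * variants$count / as.numeric(group_tot[variants$group]), 2)
  variants$total_percent <- round_half_up(100 * variants$count / grand, 2)
  variants <- variants[order(variants$group, variants$gene, -variants$count,
                             variants$variant_c), ]
  rownames(variants) <- NULL

  genes <- data.frame(gene = names(gene_tot),
                      group = unname(gene_group[names(gene_tot)]),
                      count = as.integer(gene_tot),
                      stringsAsFactors = FALSE)
  genes$within_group_percent <- round_half_up(
    100 * genes$count / as.numeric(group_tot[genes$group]), 2)
  genes$total_percent <- round_half_up(100 * genes$count / grand, 2)
  genes <- genes[order(-genes$count, genes$gene), ]
  rownames(genes) <- NULL

  groups <- data.frame(group = names(group_tot),
                       count = as.integer(group_tot),
                       stringsAsFactors = FALSE)
  groups$total_percent <- round_half_up(100 * groups$count / grand, 2)
  groups <- groups[order(-groups$count, groups$group), ]
  rownames(groups) <- NULL

  structure(list(variants = variants, genes = genes, groups = groups,
                 grand_total = grand),
            class = "nbs_spectrum")
}

#' Hotspot variants of a gene with cumulative frequency
#'
#' Ranks a gene's variants by allele count (ties broken by nucleotide HGVS
#' string) and reports each variant's relative frequency and the cumulative
#' frequency of the top variants.  Frequencies use the gene's within-group
#' denominator (so PAH hotspots are expressed against all
#' hyperphenylalaninemia alleles when the HPA grouping is active), and the
#' cumulative percentage is computed from summed counts, not from summed
#' rounded percentages.
#'
#' @param spectrum an `nbs_spectrum` object.
#' @param gene gene symbol present in the spectrum.
#' @param top_k how many top variants to report (default all).
#' @return data frame `variant_c`, `variant_p`, `count`, `within_percent`,
#'   `cumulative_percent`.
#' @examples
#' spec <- relative_frequencies(nbs_variant_counts(), nbs_group_map())
#' hotspot_summary(spec, "SLC25A13", top_k = 2)
#' @export
hotspot_summary <- function(spectrum, gene, top_k = Inf) {
  stopifnot(inherits(spectrum, "nbs_spectrum"))
  v <- spectrum$variants[spectrum$variants$gene == gene, , drop = FALSE]
  if (!nrow(v)) stop("gene '", gene, "' not present in the spectrum")
  v <- v[order(-v$count, v$variant_c), , drop = FALSE]
  k <- min(top_k, nrow(v))
  v <- v[seq_len(k), , drop = FALSE]
  denom <- spectrum$groups$count[spectrum$groups$group == v$group[1]]
  v$cumulative_percent <- round_half_up(100 * cumsum(v$count) / denom, 2)
  rownames(v) <- NULL
  v[, c("variant_c", "variant_p", "count", "within_percent",
        "cumulative_percent")]
}

#' @export
print.nbs_spectrum <- function(x, ...) {
  cat("<nbs_spectrum> ", x$grand_total, " alleles across ",
      nrow(x$genes), " genes\n", sep = "")
  print.data.frame(utils::head(x$genes, 10), row.names = FALSE)
  if (nrow(x$genes) > 10) cat("  ...\n")
  invisible(x)
}
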