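#' Remove rate categories from selected partitions
#'
#' Deletes every column of the restricted partitions whose assigned gamma
#' category is in `drop`; other partitions are untouched. Partition spans are
#' recomputed so the result is again a valid [partitioned_alignment].
#'
#' @param aln A [partitioned_alignment].
#' @param assignment A [assign_site_categories()] result covering the
#'   restricted partitions (its `site` column indexes `aln` columns).
#' @param drop Integer set of categories to remove (within 1..K).
#' @param restrict_to Partition kinds eligible for removal.
#' @return A list: `alignment` (reduced), `removed_columns` (matrix of the
#'   deleted columns, in original order), `removed_sites` (their original
#'   column indices), `fraction` (removed / restricted columns).
#' @export
remove_categories <- function(aln, assignment, drop, restrict_to = "rRNA") {
  stopifnot(inherits(aln, "partitioned_alignment"))
  K <- sum(grepl("^p_cat", names(assignment)))
  drop <- unique(as.integer(drop))
  if (length(drop) > 0 && (min(drop) < 1 || max(drop) > K)) {
    stop(sprintf("drop categories must lie in 1..%d", K), call. = FALSE)
  }
  restricted <- aln$partitions[aln$partitions$kind %in% restrict_to, , drop = FALSE]
  restricted_cols <- unlist(purrr::map2(restricted$start, restricted$end, seq.int))
  uncovered <- setdiff(restricted_cols, assignment$site)
  if (length(uncovered) > 0) {
    stop(sprintf("assignment does not cover restricted column %d", uncovered[1]),
         call. = FALSE)
  }
  rm_sites <- sort(assignment$site[assignment$category %in% drop &
                                     assignment$site %in% restricted_cols])
  if (length(rm_sites) == 0) {
    return(list(alignment = aln,
                removed_columns = aln$seq[, 0, drop = FALSE],
                removed_sites = integer(0), fraction = 0))
  }
  keep <- setdiff(seq_len(ncol(aln$seq)), rm_sites)
  new_seq <- aln$seq[, keep, drop = FALSE]
  p <- aln$partitions
  new_len <- vapply(seq_len(nrow(p)), function(i) {
    span <- seq.int(p$start[i], p$end[i])
    sum(!(span %in% rm_sites))
  }, integer(1))
  new_end <- cumsum(new_len)
  new_start <- c(1L, utils::head(new_end, -1) + 1L)
  p$start <- as.integer(new_start); p$end <- as.integer(new_end)
  p <- p[new_len > 0, , drop = FALSE]
  list(alignment = partitioned_alignment(new_seq, p),
       removed_columns = aln$seq[, rm_sites, drop = FALSE],
       removed_sites = rm_sites,
       fraction = length(rm_sites) / length(restricted_cols))
}

#' Build the DS1--DS4 saturation-reduction dataset series
#'
#' DS1 is the all-nucleotide alignment as given. DS2 translates every coding
#' partition to amino acids and keeps the rRNA partitions as nucleotides.
#' DS3 removes from DS2 the rRNA sites assigned to the fastest gamma category
#' (K); DS4 removes categories K-1 and K. Site categories come from
#' empirical-Bayes classification under GTR+Gamma on the fixed chronogram —
#' fitted per rRNA gene by default, or at supplied parameters. Removal is
#' joint across rRNA genes.
#'
#' @param aln A [partitioned_alignment] with coding and rRNA partitions.
#' @param tree A [chronogram] covering the alignment's taxa.
#' @param K Number of gamma categories.
#' @param params `NULL` (fit per gene), a single [gtr_params] reused for all
#'   rRNA genes, or a named list of per-gene [gtr_params].
#' @param per_gene Fit/classify per gene (default) or jointly on the pooled
#'   rRNA columns.
#' @return A `ds_series` list: the four alignments (`DS1`..`DS4`),
#'   `assignment` (site-category tibble in DS1 coordinates), `manifest`
#'   (one row per DS2 column: `ds2_column`, `gene`, `kind`, `category`,
#'   `dropped_in`), `removed` (the deleted DS2 columns for DS3 and DS4),
#'   `removal` (per-step fraction bookkeeping), `params`, `K`.
#' @export
build_ds_series <- function(aln, tree, K = 10, params = NULL, per_gene = TRUE) {
  stopifnot(inherits(aln, "partitioned_alignment"))
  rr <- aln$partitions[aln$partitions$kind == "rRNA", , drop = FALSE]
  if (nrow(rr) == 0) stop("alignment has no rRNA partitions", call. = FALSE)

  # --- site categories on the DS1 coordinates
  fit_params <- list()
  assignments <- list()
  if (per_gene) {
    for (g in rr$gene) {
      gp <- if (inherits(params, "gtr_params")) params
            else if (is.list(params) && !is.null(params[[g]])) params[[g]]
            else fit_gtr_gamma(gene_columns(aln, g), tree, K = K)$params
      fit_params[[g]] <- gp
      assignments[[g]] <- assign_site_categories(aln, tree, gp, K = K, genes = g)
    }
    assignment <- purrr::list_rbind(assignments)
  } else {
    gp <- if (inherits(params, "gtr_params")) params else {
      pooled <- do.call(cbind, lapply(rr$gene, function(g) gene_columns(aln, g)))
      fit_gtr_gamma(pooled, tree, K = K)$params
    }
    fit_params <- stats::setNames(rep(list(gp), nrow(rr)), rr$gene)
    assignment <- assign_site_categories(aln, tree, gp, K = K, genes = rr$gene)
  }

  # --- DS2: translate coding partitions, keep rRNA, remap columns
  blocks <- list(); parts <- list(); ds2_meta <- list()
  pos <- 1L
  for (i in seq_len(nrow(aln$partitions))) {
    p <- aln$partitions[i, ]
    cols <- gene_columns(aln, p$gene)
    if (p$kind == "coding") {
      aa <- translate_cds(cols, frame = p$frame)
      blocks[[i]] <- aa
      n <- ncol(aa)
      ds2_meta[[i]] <- tibble::tibble(
        gene = p$gene, kind = "aa", ds1_column = NA_integer_,
        category = NA_integer_, n = n)
      parts[[i]] <- tibble::tibble(gene = p$gene, kind = "aa",
                                   start = pos, end = pos + n - 1L, frame = 0L)
    } else {
      blocks[[i]] <- cols
      n <- ncol(cols)
      span <- seq.int(p$start, p$end)
      cat_here <- assignment$category[match(span, assignment$site)]
      ds2_meta[[i]] <- tibble::tibble(
        gene = p$gene, kind = p$kind, ds1_column = span,
        category = cat_here, n = 1L)
      parts[[i]] <- tibble::tibble(gene = p$gene, kind = p$kind,
                                   start = pos, end = pos + n - 1L, frame = 0L)
    }
    pos <- pos + ncol(blocks[[i]])
  }
  ds2 <- partitioned_alignment(do.call(cbind, blocks), purrr::list_rbind(parts))
  meta <- purrr::list_rbind(lapply(ds2_meta, function(m) {
    if (all(m$n == 1)) m[, c("gene", "kind", "ds1_column", "category")]
    else tibble::tibble(gene = m$gene, kind = m$kind,
                        ds1_column = rep(NA_integer_, m$n),
                        category = rep(NA_integer_, m$n))
  }))
  meta$ds2_column <- seq_len(ncol(ds2$seq))
  meta$dropped_in <- dplyr::case_when(
    meta$kind == "rRNA" & meta$category >= K ~ "DS3+DS4",
    meta$kind == "rRNA" & meta$category == K - 1 ~ "DS4",
    TRUE ~ "")
  manifest <- meta[, c("ds2_column", "gene", "kind", "ds1_column", "category", "dropped_in")]

  # --- DS3 / DS4 by joint removal over the rRNA partitions of DS2
  assign_ds2 <- tibble::tibble(
    site = manifest$ds2_column[manifest$kind == "rRNA"],
    gene = manifest$gene[manifest$kind == "rRNA"],
    category = manifest$category[manifest$kind == "rRNA"])
  for (k in seq_len(K)) assign_ds2[[paste0("p_cat", k)]] <- NA_real_
  r3 <- remove_categories(ds2, assign_ds2, drop = K, restrict_to = "rRNA")
  r4 <- remove_categories(ds2, assign_ds2, drop = c(K - 1L, K), restrict_to = "rRNA")
  n_rrna <- sum(manifest$kind == "rRNA")
  removal <- tibble::tibble(
    step = c("DS3", "DS4"),
    dropped_categories = c(paste(K), paste(c(K - 1L, K), collapse = ",")),
    n_removed = c(length(r3$removed_sites), length(r4$removed_sites)),
    n_rrna_columns = n_rrna,
    fraction = c(r3$fraction, r4$fraction))
  structure(list(DS1 = aln, DS2 = ds2, DS3 = r3$alignment, DS4 = r4$alignment,
                 assignment = assignment, manifest = manifest,
                 removed = list(DS3 = r3, DS4 = r4),
                 removal = removal, params = fit_params, K = K),
            class = "ds_series")
}

#' @export
print.ds_series <- function(x, ...) {
  cat(sprintf("Dataset series (K = %d):\n", x$K))
  for (ds in c("DS1", "DS2", "DS3", "DS4")) {
    cat(sprintf("  %s: %d taxa x %d columns\n", ds, nrow(x[[ds]]$seq), ncol(x[[ds]]$seq)))
  }
  print(x$removal)
  invisible(x)
}

#' Rebuild DS2 from a reduced dataset plus its manifest
#'
#' Lossless-bookkeeping check: reinserts the removed columns of DS3 or DS4 at
#' the positions recorded in the manifest and returns the reassembled
#' alignment matrix, which must equal DS2 exactly.
#'
#' @param series A [build_ds_series()] result.
#' @param from `"DS3"` or `"DS4"`.
#' @return Character matrix identical to `series$DS2$seq` when the manifest
#'   is intact.
#' @export
reconstruct_ds2 <- function(series, from = c("DS3", "DS4")) {
  from <- match.arg(from)
  red <- series[[from]]$seq
  removed <- series$removed[[from]]
  out <- matrix(NA_character_, nrow(red), ncol(series$DS2$seq),
                dimnames = list(rownames(red), NULL))
  out[, removed$removed_sites] <- removed$removed_columns
  out[, setdiff(seq_len(ncol(out)), removed$removed_sites)] <- red
  out
}
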