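#' Construct a community table
#'
#' The universal currency of the pipeline: a taxa x samples abundance matrix.
#' Counts are non-negative integers; relative-abundance tables are flagged
#' with `is_relative` and every sample column must sum to 1.
#'
#' @param counts numeric matrix, taxa in rows, samples in columns; rownames
#'   are taxon ids, colnames are sample ids.
#' @param is_relative logical; `TRUE` if `counts` holds relative abundances.
#' @return an object of class `community_table`.
#' @export
community_table <- function(counts, is_relative = FALSE) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix (taxa x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have taxon rownames and sample colnames")
  dup_t <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup_t))
    stop("duplicated taxon id(s): ", paste(unique(dup_t), collapse = ", "))
  dup_s <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup_s))
    stop("duplicated sample id(s): ", paste(unique(dup_s), collapse = ", "))
  if (anyNA(counts)) stop("`counts` contains missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at taxon '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (is_relative) {
    cs <- colSums(counts)
    off <- which(abs(cs - 1) > 1e-9 & cs > 0)
    if (length(off))
      stop("relative-abundance columns must sum to 1; offending sample(s): ",
           paste(colnames(counts)[off], collapse = ", "))
  }
  structure(list(counts = counts, is_relative = is_relative),
            class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d taxa x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$is_relative) "relative abundance" else "counts"))
  invisible(x)
}

#' @export
dim.community_table <- function(x) dim(x$counts)

#' Taxon and sample identifiers of a community table
#' @param table a `community_table`.
#' @return character vector of ids.
#' @export
taxon_ids <- function(table) rownames(table$counts)

#' @rdname taxon_ids
#' @export
sample_ids <- function(table) colnames(table$counts)

#' Read / write a community table
#'
#' TSV dialect: taxa in rows, samples in columns, header row of sample ids,
#' first column taxon ids. BIOM-style JSON: dense matrix with `rows`,
#' `columns` and `data` fields. Both round-trip losslessly, including
#' all-zero taxa.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom-json"`.
#' @param is_relative logical flag passed to [community_table()].
#' @return [read_community()] a `community_table`; [write_community()] the
#'   path, invisibly.
#' @export
read_community <- function(path, format = c("tsv", "biom-json"),
                           is_relative = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("malformed header: need taxon-id column plus >=1 sample column")
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric abundance values in ", path)
    rownames(m) <- ids
  } else {
    b <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    ids <- vapply(b$rows, function(r) r$id, character(1))
    sids <- vapply(b$columns, function(s) s$id, character(1))
    m <- do.call(rbind, lapply(b$data, function(r) as.numeric(unlist(r))))
    rownames(m) <- ids
    colnames(m) <- sids
  }
  community_table(m, is_relative = is_relative)
}

#' @rdname read_community
#' @param table a `community_table` to write.
#' @export
write_community <- function(table, path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "community_table"))
  if (format == "tsv") {
    df <- data.frame(taxon_id = taxon_ids(table), table$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    b <- list(
      id = "pitmudr", format = "dense", type = "OTU table",
      shape = dim(table$counts),
      rows = lapply(taxon_ids(table), function(i) list(id = i)),
      columns = lapply(sample_ids(table), function(i) list(id = i)),
      data = unname(split(table$counts, row(table$counts)))
    )
    jsonlite::write_json(b, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) to a common depth; samples whose total falls below the
#' depth are dropped with a warning. Column sums of the result equal the
#' depth exactly, and identical seeds give identical output.
#'
#' @param table `community_table` of counts.
#' @param depth positive integer target depth per sample.
#' @param seed integer seed.
#' @return rarefied `community_table`; dropped sample ids are attached as
#'   attribute `"dropped"`.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  stopifnot(inherits(table, "community_table"))
  if (table$is_relative) stop("rarefaction requires counts, not relative abundances")
  if (length(depth) != 1 || depth <= 0 || depth != round(depth))
    stop("`depth` must be a positive integer")
  x <- table$counts
  if (any(x != round(x))) stop("rarefaction requires integer counts")
  tot <- colSums(x)
  keep <- tot >= depth
  if (!any(keep)) stop("all samples fall below depth ", depth)
  dropped <- colnames(x)[!keep]
  if (length(dropped))
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    length(dropped), depth, paste(dropped, collapse = ", ")))
  x <- x[, keep, drop = FALSE]
  set.seed(seed)
  out <- apply(x, 2, function(col) {
    reads <- rep.int(seq_along(col), col)
    picked <- if (length(reads) == depth) reads else sample(reads, depth)
    tabulate(picked, nbins = length(col))
  })
  rownames(out) <- rownames(x)
  res <- community_table(out, is_relative = FALSE)
  attr(res, "dropped") <- dropped
  res
}

#' Convert counts to relative abundances
#'
#' @param table `community_table`.
#' @return `community_table` with `is_relative = TRUE`; columns sum to 1.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "community_table"))
  if (table$is_relative) return(table)
  cs <- colSums(table$counts)
  if (any(cs == 0)) stop("empty sample(s): ",
                         paste(colnames(table$counts)[cs == 0], collapse = ", "))
  community_table(sweep(table$counts, 2, cs, "/"), is_relative = TRUE)
}

.rank_ladder <- c("phylum", "class", "order", "family", "genus")

#' Read a taxonomy table
#'
#' TSV with columns `taxon_id`, `phylum`, `class`, `order`, `family`,
#' `genus`; empty strings are treated as unassigned.
#'
#' @param path file path.
#' @return data.frame keyed by `taxon_id`.
#' @export
read_taxonomy <- function(path) {
  tx <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("taxon_id", .rank_ladder)
  miss <- setdiff(need, names(tx))
  if (length(miss)) stop("taxonomy missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tx$taxon_id)) stop("duplicated taxon_id in taxonomy")
  tx[tx == ""] <- NA
  tx
}

#' Aggregate a community table at a taxonomic rank
#'
#' Member taxa sharing a rank value are summed; taxa unassigned at the rank
#' (or absent from the taxonomy) pool into an explicit `"unassigned"` row so
#' that per-sample totals are conserved.
#'
#' @param table `community_table`.
#' @param taxonomy data.frame as from [read_taxonomy()].
#' @param rank one of `"phylum"`, `"class"`, `"order"`, `"family"`, `"genus"`.
#' @return aggregated `community_table` with rank values as taxon ids.
#' @export
aggregate_taxa <- function(table, taxonomy, rank) {
  stopifnot(inherits(table, "community_table"))
  if (!rank %in% .rank_ladder)
    stop("`rank` must be one of: ", paste(.rank_ladder, collapse = ", "))
  lab <- taxonomy[[rank]][match(taxon_ids(table), taxonomy$taxon_id)]
  lab[is.na(lab)] <- "unassigned"
  agg <- rowsum(table$counts, group = lab, reorder = TRUE)
  community_table(agg, is_relative = table$is_relative)
}

#' Filter taxa by prevalence and mean relative abundance
#'
#' Retains taxa present (abundance > 0) in at least `min_prevalence` of
#' samples and with mean relative abundance at least `min_mean_ra`.
#'
#' @param table relative-abundance `community_table`.
#' @param min_prevalence fraction in \[0, 1\].
#' @param min_mean_ra fraction in \[0, 1\].
#' @return filtered `community_table`; removed taxon ids attached as
#'   attribute `"removed"`.
#' @export
filter_prevalence <- function(table, min_prevalence = 0.2, min_mean_ra = 1e-4) {
  stopifnot(inherits(table, "community_table"))
  if (!table$is_relative) stop("filter_prevalence expects a relative table")
  if (min_prevalence < 0 || min_prevalence > 1 || min_mean_ra < 0 || min_mean_ra > 1)
    stop("thresholds must lie in [0, 1]")
  prev <- rowMeans(table$counts > 0)
  mra <- rowMeans(table$counts)
  keep <- prev >= min_prevalence & mra >= min_mean_ra
  res <- structure(list(counts = table$counts[keep, , drop = FALSE],
                        is_relative = TRUE),
                   class = "community_table")
  attr(res, "removed") <- taxon_ids(table)[!keep]
  res
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `age_group` (Aa/Ab/Ac/Ad), `age_years`,
#' `longitude_group` (La/Lb/Lc/Ld), `longitude_deg`. Age groups become an
#' ordered factor Aa < Ab < Ac < Ad.
#'
#' @param path file path.
#' @param table optional `community_table`; if given, every sample must have
#'   a metadata row.
#' @return data.frame keyed by `sample_id`.
#' @export
read_sample_frame <- function(path, table = NULL) {
  sf <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  sample_frame(sf, table = table)
}

#' Validate a sample metadata frame
#'
#' @param sf data.frame with at least `sample_id`, `age_group`,
#'   `longitude_group`.
#' @inheritParams read_sample_frame
#' @return validated data.frame with ordered `age_group`.
#' @export
sample_frame <- function(sf, table = NULL) {
  need <- c("sample_id", "age_group", "longitude_group")
  miss <- setdiff(need, names(sf))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(sf$sample_id)) stop("duplicated sample_id in metadata")
  bad <- setdiff(unique(as.character(sf$age_group)), c("Aa", "Ab", "Ac", "Ad"))
  if (length(bad)) stop("unknown age_group value(s): ", paste(bad, collapse = ", "))
  sf$age_group <- factor(sf$age_group, levels = c("Aa", "Ab", "Ac", "Ad"),
                         ordered = TRUE)
  badl <- setdiff(unique(as.character(sf$longitude_group)),
                  c("La", "Lb", "Lc", "Ld"))
  if (length(badl)) stop("unknown longitude_group value(s): ",
                         paste(badl, collapse = ", "))
  sf$longitude_group <- factor(sf$longitude_group,
                               levels = c("La", "Lb", "Lc", "Ld"))
  if (!is.null(table)) {
    missing <- setdiff(sample_ids(table), sf$sample_id)
    if (length(missing))
      stop("sample(s) without metadata: ", paste(missing, collapse = ", "))
  }
  sf
}

#' Representative numeric ages for the cellar-age groups
#'
#' Maps Aa/Ab/Ac/Ad to representative ages in years for temporal-trend
#' regression when exact ages are absent (Aa < 10 y, Ab 10-50 y, Ac ~100 y,
#' Ad ~300-400 y).
#'
#' @param age_group factor/character of group labels.
#' @param ages named numeric vector of representative ages.
#' @return numeric vector of ages in years.
#' @export
age_group_years <- function(age_group,
                            ages = c(Aa = 5, Ab = 30, Ac = 100, Ad = 350)) {
  unname(ages[as.character(age_group)])
}

#' Restrict a table and tree to their shared taxa
#'
#' Taxa absent from the phylogeny are excluded from tree-based stages only;
#' the dropped ids are reported via attribute `"dropped_taxa"`.
#'
#' @param table `community_table`.
#' @param tree `ape::phylo` with tip labels matching taxon ids.
#' @return list with elements `table` (restricted) and `tree` (pruned).
#' @export
match_tree <- function(table, tree) {
  stopifnot(inherits(table, "community_table"), inherits(tree, "phylo"))
  shared <- intersect(taxon_ids(table), tree$tip.label)
  if (!length(shared)) stop("no taxa shared between table and tree")
  dropped <- setdiff(taxon_ids(table), shared)
  tab <- structure(list(counts = table$counts[shared, , drop = FALSE],
                        is_relative = FALSE), class = "community_table")
  if (table$is_relative) tab <- to_relative(tab)
  tr <- if (length(setdiff(tree$tip.label, shared)))
    ape::keep.tip(tree, shared) else tree
  res <- list(table = tab, tree = tr)
  attr(res, "dropped_taxa") <- dropped
  res
}
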