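#' Gene model: transcript-to-exon-set structure of one gene
#'
#' Exon identity is exact coordinate equality: an exon is the tuple
#' (chromosome, start, end, strand) in 1-based inclusive GTF coordinates,
#' encoded as the key `"chrom:start-end:strand"`. Duplicate exon records
#' collapse to one exon. All exons of a gene must lie on one chromosome and
#' every transcript must carry at least one exon.
#'
#' @param gene_id gene accession.
#' @param transcripts named list mapping transcript id to a character vector
#'   of exon keys.
#' @param exons data.frame with columns `key`, `chrom`, `start`, `end`,
#'   `strand` describing every distinct exon referenced.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcripts, exons) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  if (length(transcripts) == 0L || is.null(names(transcripts)))
    stop("gene_model: transcripts must be a non-empty named list")
  if (anyDuplicated(names(transcripts)))
    stop("gene_model: duplicate transcript ids within gene ", gene_id)
  transcripts <- lapply(transcripts, function(e) unique(as.character(e)))
  if (any(lengths(transcripts) == 0L))
    stop("gene_model: transcript with no exons in gene ", gene_id)
  exons <- as.data.frame(exons)
  stopifnot(all(c("key", "chrom", "start", "end", "strand") %in% names(exons)))
  used <- unique(unlist(transcripts, use.names = FALSE))
  if (!all(used %in% exons$key))
    stop("gene_model: transcript references unknown exon in gene ", gene_id)
  if (length(unique(exons$chrom[exons$key %in% used])) > 1L)
    stop("gene_model: exons of gene ", gene_id, " span multiple chromosomes")
  structure(list(gene_id = gene_id, transcripts = transcripts,
                 exons = exons[exons$key %in% used, , drop = FALSE]),
            class = "gene_model")
}

#' @exportS3Method base::print
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s: %d transcript(s), %d distinct exon(s)\n",
              x$gene_id, length(x$transcripts), nrow(x$exons)))
  invisible(x)
}

.exon_key <- function(chrom, start, end, strand) {
  paste0(chrom, ":", start, "-", end, ":", strand)
}

#' Read gene models from a GTF file
#'
#' Parses exon features (via `rtracklayer`) into one [gene_model()] per
#' `gene_id`. Exon identity is exact coordinate equality, so duplicated exon
#' lines collapse.
#'
#' @param gtf_path path to a GTF file whose exon features carry `gene_id`
#'   and `transcript_id` attributes.
#' @return named list of [gene_model()] objects (names are gene ids, in
#'   order of first appearance).
#' @export
read_gene_models <- function(gtf_path) {
  if (!file.exists(gtf_path)) stop("read_gene_models: file not found: ", gtf_path)
  gr <- tryCatch(rtracklayer::import(gtf_path, format = "gtf"),
                 error = function(e)
                   stop("read_gene_models: failed to parse GTF '", gtf_path,
                        "': ", conditionMessage(e), call. = FALSE))
  meta <- S4Vectors::mcols(gr)
  if (!"type" %in% names(meta)) stop("read_gene_models: GTF lacks feature types")
  ex <- gr[meta$type == "exon"]
  if (length(ex) == 0L) stop("read_gene_models: no exon features in ", gtf_path)
  em <- S4Vectors::mcols(ex)
  if (!all(c("gene_id", "transcript_id") %in% names(em)) ||
      anyNA(em$gene_id) || anyNA(em$transcript_id))
    stop("read_gene_models: exon feature without gene_id/transcript_id attribute")
  df <- data.frame(
    gene_id = as.character(em$gene_id),
    transcript_id = as.character(em$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex),
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    stringsAsFactors = FALSE)
  df$key <- .exon_key(df$chrom, df$start, df$end, df$strand)
  models <- lapply(split(df, factor(df$gene_id, levels = unique(df$gene_id))),
                   function(g) {
    tx <- lapply(split(g$key, factor(g$transcript_id,
                                     levels = unique(g$transcript_id))),
                 unique)
    exons <- unique(g[, c("key", "chrom", "start", "end", "strand")])
    gene_model(g$gene_id[1], tx, exons)
  })
  all_tx <- unlist(lapply(models, function(m) names(m$transcripts)),
                   use.names = FALSE)
  if (anyDuplicated(all_tx))
    stop("read_gene_models: transcript id assigned to multiple genes: ",
         paste(unique(all_tx[duplicated(all_tx)]), collapse = ", "))
  models
}

#' Write gene models to a GTF file
#'
#' One exon feature line per (transcript, exon); inverse of
#' [read_gene_models()] up to line order.
#' @param models list of [gene_model()] objects.
#' @param path output GTF path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gtf <- function(models, path) {
  rows <- do.call(rbind, lapply(models, function(m) {
    ex <- m$exons
    do.call(rbind, lapply(names(m$transcripts), function(t) {
      e <- ex[match(m$transcripts[[t]], ex$key), , drop = FALSE]
      data.frame(chrom = e$chrom, start = e$start, end = e$end,
                 strand = e$strand, gene_id = m$gene_id, transcript_id = t,
                 stringsAsFactors = FALSE)
    }))
  }))
  gr <- GenomicRanges::GRanges(
    seqnames = rows$chrom,
    ranges = IRanges::IRanges(start = rows$start, end = rows$end),
    strand = rows$strand)
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$source <- "lfcmm"
  S4Vectors::mcols(gr)$gene_id <- rows$gene_id
  S4Vectors::mcols(gr)$transcript_id <- rows$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Expression vector of per-transcript log2 fold changes
#'
#' @param ids transcript accessions (unique).
#' @param values finite log2 fold changes, one per id.
#' @return named numeric vector of class `expression_vector`.
#' @export
expression_vector <- function(ids, values) {
  ids <- as.character(ids)
  values <- as.numeric(values)
  if (length(ids) != length(values)) stop("expression_vector: length mismatch")
  if (length(ids) < 2L) stop("expression_vector: need at least 2 observations")
  if (anyDuplicated(ids))
    stop("expression_vector: duplicate ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression_vector: non-finite log2FC values")
  structure(stats::setNames(values, ids), class = "expression_vector")
}

#' @exportS3Method base::print
print.expression_vector <- function(x, ...) {
  cat(sprintf("expression_vector: %d transcripts, mean %.4g, sd %.4g\n",
              length(x), mean(x), stats::sd(x)))
  invisible(x)
}

#' Read a two-column log2 fold change table
#'
#' Tab-separated, columns (transcript id, log2FC); a header line is detected
#' and skipped when its second field is not numeric.
#' @param tsv_path path to the TSV file.
#' @return an [expression_vector()] in file order.
#' @export
read_expression_table <- function(tsv_path) {
  if (!file.exists(tsv_path)) stop("read_expression_table: file not found: ", tsv_path)
  lines <- readLines(tsv_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("read_expression_table: empty file: ", tsv_path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("read_expression_table: line without two tab-separated fields")
  second <- vapply(parts, `[[`, character(1), 2L)
  has_header <- is.na(suppressWarnings(as.numeric(second[1])))
  if (has_header) {
    parts <- parts[-1]
    second <- second[-1]
    if (length(parts) == 0L) stop("read_expression_table: no data rows")
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  vals <- suppressWarnings(as.numeric(second))
  if (anyNA(vals))
    stop("read_expression_table: non-numeric log2FC value (row ",
         which(is.na(vals))[1], ")")
  expression_vector(ids, vals)
}

#' Term mapping: transcript-to-term assignments and term gene sets
#'
#' @param kind one of `"gene"`, `"go"`, `"reactome"`.
#' @param assignments named list mapping transcript id to a character vector
#'   of level identifiers (gene ids, GO ids or Reactome stable ids).
#' @param level_universe named list mapping level identifier to the set of
#'   gene ids it contains (required for kinds `go`/`reactome`; used for the
#'   term-overlap Jaccard covariance).
#' @param tx2gene optional named character vector transcript id -> gene id;
#'   carried along so term gene sets can be re-derived after filtering.
#' @return an object of class `term_mapping`.
#' @export
term_mapping <- function(kind = c("gene", "go", "reactome"), assignments,
                         level_universe = NULL, tx2gene = NULL) {
  kind <- match.arg(kind)
  if (length(assignments) == 0L || is.null(names(assignments)))
    stop("term_mapping: assignments must be a non-empty named list")
  assignments <- lapply(assignments, function(x) unique(as.character(x)))
  if (any(lengths(assignments) == 0L))
    stop("term_mapping: transcript with empty level set")
  if (kind != "gene") {
    if (is.null(level_universe))
      stop("term_mapping: level_universe required for kind ", kind)
    level_universe <- lapply(level_universe, function(x) unique(as.character(x)))
    if (any(lengths(level_universe) == 0L))
      stop("term_mapping: term with empty gene set")
    lv <- unique(unlist(assignments, use.names = FALSE))
    if (!all(lv %in% names(level_universe)))
      stop("term_mapping: assigned level missing from level_universe: ",
           paste(setdiff(lv, names(level_universe))[1:3], collapse = ", "))
  }
  structure(list(kind = kind, assignments = assignments,
                 level_universe = level_universe, tx2gene = tx2gene),
            class = "term_mapping")
}

#' @exportS3Method base::print
print.term_mapping <- function(x, ...) {
  cat(sprintf("term_mapping (%s): %d transcripts -> %d levels\n", x$kind,
              length(x$assignments),
              length(unique(unlist(x$assignments, use.names = FALSE)))))
  invisible(x)
}

#' Read a transcript/gene-to-term mapping table
#'
#' Accepts either a two-column TSV (`id`, `term id`) or the six-column
#' Ensembl2Reactome layout (`gene id`, `pathway id`, URL, name, evidence,
#' species). Gene-keyed mappings (Reactome layout, or `id_type = "gene"`)
#' are expanded so every transcript inherits its gene's terms via `tx2gene`.
#' The `level_universe` (term -> gene set) is built by inverting the mapping
#' at the gene level.
#'
#' @param tsv_path path to the mapping table (no header for the two-column
#'   layout; a header is tolerated for the six-column layout).
#' @param kind `"gene"`, `"go"` or `"reactome"`.
#' @param tx2gene named character vector transcript id -> gene id; required
#'   for kinds `go`/`reactome`.
#' @param id_type whether the first column holds transcript or gene ids;
#'   `"auto"` uses gene ids for six-column files and for kind `"reactome"`,
#'   transcript ids otherwise.
#' @return a [term_mapping()].
#' @export
read_term_mapping <- function(tsv_path, kind = c("gene", "go", "reactome"),
                              tx2gene = NULL,
                              id_type = c("auto", "transcript", "gene")) {
  kind <- match.arg(kind)
  id_type <- match.arg(id_type)
  if (!file.exists(tsv_path)) stop("read_term_mapping: file not found: ", tsv_path)
  lines <- readLines(tsv_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("read_term_mapping: empty mapping file: ", tsv_path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 2L)) stop("read_term_mapping: line without two fields")
  six_col <- all(ncols >= 6L)
  ids <- vapply(parts, `[[`, character(1), 1L)
  terms <- vapply(parts, `[[`, character(1), 2L)
  if (id_type == "auto") id_type <-
    if (six_col || kind == "reactome") "gene" else "transcript"

  if (kind == "gene") {
    if (id_type != "transcript")
      stop("read_term_mapping: kind 'gene' expects a transcript -> gene table")
    asn <- lapply(split(terms, factor(ids, levels = unique(ids))), unique)
    if (any(lengths(asn) > 1L))
      stop("read_term_mapping: transcript assigned to multiple genes")
    genes <- unique(terms)
    return(term_mapping("gene", asn,
                        level_universe = stats::setNames(as.list(genes), genes),
                        tx2gene = stats::setNames(unlist(asn), names(asn))))
  }

  if (is.null(tx2gene))
    stop("read_term_mapping: tx2gene required for kind ", kind)
  if (is.null(names(tx2gene))) stop("read_term_mapping: tx2gene must be named")

  if (id_type == "gene") {
    gene2term <- split(terms, factor(ids, levels = unique(ids)))
    tx_keep <- names(tx2gene)[tx2gene %in% names(gene2term)]
    if (length(tx_keep) == 0L)
      stop("read_term_mapping: no transcript maps to an annotated gene")
    asn <- lapply(tx2gene[tx_keep], function(g) unique(gene2term[[g]]))
    names(asn) <- tx_keep
  } else {
    unknown <- setdiff(unique(ids), names(tx2gene))
    if (length(unknown) > 0L)
      stop("read_term_mapping: transcript mapped to unknown gene: ",
           paste(unknown[1:min(3, length(unknown))], collapse = ", "))
    asn <- lapply(split(terms, factor(ids, levels = unique(ids))), unique)
  }
  term_mapping(kind, asn,
               level_universe = .invert_to_gene_sets(asn, tx2gene),
               tx2gene = tx2gene)
}

# term -> gene set, by inverting transcript -> terms through tx2gene
.invert_to_gene_sets <- function(assignments, tx2gene) {
  tx <- rep.int(names(assignments), lengths(assignments))
  tm <- unlist(assignments, use.names = FALSE)
  gn <- unname(tx2gene[tx])
  if (anyNA(gn)) stop("term mapping references transcript absent from tx2gene")
  lapply(split(gn, tm), unique)
}

#' Parse a minimal OBO 1.2 ontology file
#'
#' Reads `[Term]` stanzas and retains `id`, `name`, `namespace`, `is_a`
#' parents and the obsolete flag. Only the fields needed for hierarchy-level
#' filtering are kept.
#'
#' @param obo_path path to the OBO file.
#' @return list with elements `id`, `name`, `namespace` (character vectors)
#'   and `parents` (named list of `is_a` parent ids), obsolete terms removed.
#' @export
parse_obo <- function(obo_path) {
  if (!file.exists(obo_path)) stop("parse_obo: file not found: ", obo_path)
  lines <- readLines(obo_path)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0L) stop("parse_obo: no [Term] stanzas in ", obo_path)
  bounds <- c(starts, length(lines) + 1L)
  terms <- list()
  for (k in seq_along(starts)) {
    chunk <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    chunk <- chunk[nzchar(chunk) & !startsWith(chunk, "[")]
    getv <- function(tag) sub(paste0("^", tag, ": *"), "",
                              chunk[startsWith(chunk, paste0(tag, ":"))])
    id <- getv("id")[1]
    if (is.na(id)) next
    if (any(grepl("^is_obsolete: *true", chunk))) next
    parents <- sub(" *!.*$", "", getv("is_a"))
    terms[[id]] <- list(name = getv("name")[1],
                        namespace = getv("namespace")[1],
                        parents = parents)
  }
  if (length(terms) == 0L) stop("parse_obo: no usable terms in ", obo_path)
  list(id = names(terms),
       name = vapply(terms, function(t) t$name %||% NA_character_, character(1)),
       namespace = vapply(terms, function(t) t$namespace %||% NA_character_,
                          character(1)),
       parents = lapply(terms, `[[`, "parents"))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1])) b else a

#' Filter or lift term annotations to one ontology hierarchy level
#'
#' The hierarchy level of a term is its minimum `is_a` path length from the
#' ontology root (`biological_process` for GO), the root itself being level
#' 0. Terms already at `level` are retained; annotations to deeper terms are
#' propagated up to all of their level-`level` ancestors (a term may map to
#' several ancestors); terms shallower than `level` are dropped. Terms
#' absent from the ontology are dropped with a warning reporting the count.
#'
#' @param mapping a [term_mapping()] of kind `go` (or `reactome` with an
#'   OBO-style hierarchy).
#' @param obo_path path to the ontology OBO file.
#' @param level non-negative integer; `level = 0` collapses everything to
#'   the root.
#' @param root optional root term id; defaults to `GO:0008150` when present,
#'   otherwise the unique term without `is_a` parents.
#' @return a [term_mapping()] over the level-`level` terms, with
#'   `level_universe` rebuilt by inverting the new assignments.
#' @export
filter_terms_by_level <- function(mapping, obo_path, level, root = NULL) {
  stopifnot(inherits(mapping, "term_mapping"), level >= 0)
  if (is.null(mapping$tx2gene))
    stop("filter_terms_by_level: mapping lacks tx2gene (needed to rebuild gene sets)")
  onto <- parse_obo(obo_path)
  keep_ns <- if (any(onto$namespace == "biological_process", na.rm = TRUE))
    which(onto$namespace == "biological_process") else seq_along(onto$id)
  ids <- onto$id[keep_ns]
  edges <- do.call(rbind, lapply(ids, function(i) {
    p <- intersect(onto$parents[[i]], ids)
    if (length(p) == 0L) return(NULL)
    cbind(i, p)
  }))
  g <- igraph::graph_from_data_frame(
    if (is.null(edges)) data.frame(from = character(), to = character())
    else data.frame(from = edges[, 1], to = edges[, 2]),
    directed = TRUE, vertices = data.frame(name = ids))
  if (is.null(root))
    root <- if ("GO:0008150" %in% ids) "GO:0008150" else {
      cand <- ids[igraph::degree(g, mode = "out") == 0L]
      if (length(cand) != 1L)
        stop("filter_terms_by_level: ambiguous ontology root (",
             length(cand), " candidates); supply `root`")
      cand
    }
  # depth = min is_a path length to the root (edges point child -> parent)
  depth <- as.vector(igraph::distances(g, v = igraph::V(g), to = root,
                                       mode = "out"))
  names(depth) <- ids
  at_level <- ids[is.finite(depth) & depth == level]
  if (length(at_level) == 0L)
    stop("filter_terms_by_level: no terms at level ", level)
  # every upward-reachable ancestor at depth `level` is a valid target
  lift <- function(term) {
    if (!term %in% ids) return(character(0))
    d <- depth[[term]]
    if (!is.finite(d) || d < level) return(character(0))
    if (d == level) return(term)
    anc <- names(igraph::subcomponent(g, term, mode = "out"))
    intersect(anc, at_level)
  }
  all_terms <- unique(unlist(mapping$assignments, use.names = FALSE))
  missing_n <- sum(!all_terms %in% ids)
  if (missing_n > 0L)
    warning("filter_terms_by_level: ", missing_n,
            " annotated term(s) absent from the ontology; dropped")
  lifted <- stats::setNames(lapply(all_terms, lift), all_terms)
  new_asn <- lapply(mapping$assignments, function(terms)
    unique(unlist(lifted[terms], use.names = FALSE)))
  new_asn <- new_asn[lengths(new_asn) > 0L]
  if (length(new_asn) == 0L)
    stop("filter_terms_by_level: no annotations survive at level ", level)
  term_mapping(mapping$kind, new_asn,
               level_universe = .invert_to_gene_sets(new_asn, mapping$tx2gene),
               tx2gene = mapping$tx2gene)
}

#' Transcript-to-gene map from gene models
#'
#' @param models list of [gene_model()] objects.
#' @return named character vector transcript id -> gene id.
#' @export
tx2gene_map <- function(models) {
  ids <- unlist(lapply(models, function(m) names(m$transcripts)),
                use.names = FALSE)
  genes <- unlist(lapply(models, function(m)
    rep(m$gene_id, length(m$transcripts))), use.names = FALSE)
  if (anyDuplicated(ids)) stop("tx2gene_map: duplicate transcript ids")
  stats::setNames(genes, ids)
}
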