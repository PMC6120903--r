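#' Construct a genome annotation
#'
#' A genome annotation holds the ordered gene intervals of a (single-replicon)
#' reference genome together with a synonym map from gene aliases (for
#' example b-numbers) to canonical names. It backs site-name normalization,
#' deletion-span expansion, length-proportional null models and window scans.
#'
#' @param genes data.frame with columns `name`, `start`, `end` (1-based,
#'   inclusive, `start <= end`). Rows may be given in any order; they are
#'   sorted by `start`.
#' @param genome_length total genome length in bases; defaults to the largest
#'   gene end coordinate.
#' @param synonyms named character vector mapping alias -> canonical name, or
#'   `NULL`.
#' @return an object of class `genome_annotation`: a list with elements
#'   `genome_length`, `genes` (sorted data.frame) and `synonym_map`.
#' @examples
#' ann <- genome_annotation(data.frame(name = c("a", "b"),
#'                                     start = c(1, 600), end = c(500, 900)),
#'                          genome_length = 1000,
#'                          synonyms = c(b0001 = "a"))
#' normalize_site_name("b0001", ann)
#' @export
genome_annotation <- function(genes, genome_length = NULL, synonyms = NULL) {
  if (!is.data.frame(genes) || !all(c("name", "start", "end") %in% names(genes)))
    stopf("`genes` must be a data.frame with columns name, start, end")
  genes <- data.frame(name = as.character(genes$name),
                      start = as.integer(genes$start),
                      end = as.integer(genes$end),
                      stringsAsFactors = FALSE)
  if (anyNA(genes)) stopf("gene table contains missing values")
  if (any(genes$start > genes$end)) stopf("gene intervals must have start <= end")
  if (anyDuplicated(genes$name)) stopf("gene names must be unique")
  genes <- genes[order(genes$start, genes$end), , drop = FALSE]
  rownames(genes) <- NULL
  genome_length <- as.integer(genome_length %||% max(genes$end))
  if (genome_length < max(genes$end)) stopf("genome_length shorter than last gene end")
  synonym_map <- character(0)
  if (!is.null(synonyms) && length(synonyms)) {
    if (is.null(names(synonyms)) || any(!nzchar(names(synonyms))))
      stopf("`synonyms` must be a named character vector (alias -> canonical)")
    bad <- setdiff(unique(unname(synonyms)), genes$name)
    if (length(bad)) stopf("synonyms point to unknown genes: %s", paste(bad, collapse = ", "))
    synonym_map <- synonyms
  }
  structure(list(genome_length = genome_length, genes = genes,
                 synonym_map = synonym_map),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes, genome length %d bp, %d synonyms\n",
              nrow(x$genes), x$genome_length, length(x$synonym_map)))
  invisible(x)
}

#' Read a genome annotation from GFF3 or a coordinate table
#'
#' GFF3 input is parsed with [ape::read.gff]; `gene` features provide the
#' intervals, the `Name` attribute (falling back to `gene` or `ID`) provides
#' the canonical name and comma-separated `Alias` attributes populate the
#' synonym map. The genome length is taken from the `##sequence-region`
#' pragma when present. A plain tab-separated file with header columns
#' `name`, `start`, `end` is accepted as a fallback.
#'
#' @param path file path (`.gff`/`.gff3` or TSV).
#' @return a [genome_annotation].
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gff <- ape::read.gff(path, GFF3 = TRUE)
    gff <- gff[gff$type == "gene", , drop = FALSE]
    if (!nrow(gff)) stopf("no gene features in %s", path)
    attr_field <- function(attrs, key) {
      m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))
      vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, character(1))
    }
    name <- attr_field(gff$attributes, "Name")
    name <- ifelse(is.na(name), attr_field(gff$attributes, "gene"), name)
    name <- ifelse(is.na(name), attr_field(gff$attributes, "ID"), name)
    if (anyNA(name)) stopf("gene feature without Name/gene/ID attribute in %s", path)
    alias <- attr_field(gff$attributes, "Alias")
    syn <- NULL
    has_alias <- which(!is.na(alias))
    if (length(has_alias)) {
      parts <- strsplit(alias[has_alias], ",", fixed = TRUE)
      syn <- setNames(rep(name[has_alias], lengths(parts)), unlist(parts))
    }
    glen <- NULL
    hdr <- readLines(path, n = 50L)
    sr <- grep("^##sequence-region", hdr, value = TRUE)
    if (length(sr)) glen <- as.integer(strsplit(sr[1], "[[:space:]]+")[[1]][4])
    genome_annotation(data.frame(name = name, start = gff$start, end = gff$end),
                      genome_length = glen, synonyms = syn)
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("name", "start", "end") %in% names(tab)))
      stopf("TSV annotation needs columns name, start, end")
    genome_annotation(tab[, c("name", "start", "end")])
  }
}

#' Write a genome annotation as GFF3
#'
#' Emits one `gene` feature per annotated gene with `ID`/`Name` attributes
#' (and `Alias` where synonyms exist), plus a `##sequence-region` pragma, so
#' the file round-trips through [read_annotation()].
#'
#' @param annotation a [genome_annotation].
#' @param path output file path.
#' @param seqid sequence identifier used in column 1.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path, seqid = "chr") {
  stopifnot(inherits(annotation, "genome_annotation"))
  g <- annotation$genes
  alias_of <- split(names(annotation$synonym_map), unname(annotation$synonym_map))
  attrs <- vapply(seq_len(nrow(g)), function(i) {
    a <- sprintf("ID=%s;Name=%s", g$name[i], g$name[i])
    al <- alias_of[[g$name[i]]]
    if (length(al)) a <- paste0(a, ";Alias=", paste(al, collapse = ","))
    a
  }, character(1))
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", seqid, annotation$genome_length),
             sprintf("%s\tevoforecast\tgene\t%d\t%d\t.\t+\t.\t%s",
                     seqid, g$start, g$end, attrs))
  writeLines(lines, path)
  invisible(path)
}

resolve_gene <- function(raw, annotation) {
  if (raw %in% annotation$genes$name) return(raw)
  hit <- annotation$synonym_map[raw]
  if (!is.na(hit) && length(hit)) return(unname(hit))
  stopf("gene name or alias not found in annotation: '%s'", raw)
}

#' Normalize a genome-site name
#'
#' Canonical site names use the annotation's gene names; aliases are resolved
#' through the synonym map. Intergenic sites are written as the two flanking
#' genes joined by a dash in genome coordinate order. Insertion-sequence (IS)
#' involvement is recorded by appending the element name after `::`.
#' Normalization is idempotent: applying it to a canonical name returns the
#' name unchanged.
#'
#' @param raw site name as reported (gene, alias, or `flankA-flankB`).
#' @param annotation a [genome_annotation], or `NULL` to accept `raw` as
#'   already canonical (aliases then raise no error and no reordering is
#'   possible).
#' @param is_element optional IS element name to tag the site with.
#' @return canonical site name (character scalar).
#' @examples
#' ann <- genome_annotation(data.frame(name = c("pyrE", "rph"),
#'                                     start = c(100, 900), end = c(700, 1500)),
#'                          synonyms = c(b3642 = "rph"))
#' normalize_site_name("rph-pyrE", ann)   # -> "pyrE-rph"
#' normalize_site_name("b3642", ann)      # -> "rph"
#' @export
normalize_site_name <- function(raw, annotation = NULL, is_element = NULL) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw))
    stopf("`raw` must be a non-empty character scalar")
  tag <- NULL
  if (grepl(IS_SEPARATOR, raw, fixed = TRUE)) {
    bits <- strsplit(raw, IS_SEPARATOR, fixed = TRUE)[[1]]
    if (length(bits) != 2L) stopf("malformed IS-tagged site name: '%s'", raw)
    raw <- bits[1]
    tag <- bits[2]
  }
  if (!is.null(is_element) && !is.na(is_element) && nzchar(is_element)) {
    if (!is.null(tag) && !identical(tag, as.character(is_element)))
      stopf("conflicting IS tags for site '%s': '%s' vs '%s'", raw, tag, is_element)
    tag <- as.character(is_element)
  }
  core <- if (grepl("-", raw, fixed = TRUE)) {
    flanks <- strsplit(raw, "-", fixed = TRUE)[[1]]
    if (length(flanks) != 2L || any(!nzchar(flanks)))
      stopf("intergenic site must be 'flankA-flankB': '%s'", raw)
    if (is.null(annotation)) paste(flanks, collapse = "-")
    else {
      flanks <- vapply(flanks, resolve_gene, character(1), annotation = annotation)
      starts <- annotation$genes$start[match(flanks, annotation$genes$name)]
      paste(flanks[order(starts)], collapse = "-")
    }
  } else {
    if (is.null(annotation)) raw else resolve_gene(raw, annotation)
  }
  if (is.null(tag)) core else paste0(core, IS_SEPARATOR, tag)
}

#' Expand a deletion span to the genes it covers
#'
#' Publications sometimes report a large deletion only by its two flanking
#' genes; the genes in between are recovered from the reference annotation.
#' The flanks themselves are included and the result is in genome order
#' regardless of the order the flanks are given in.
#'
#' @param flank_a,flank_b gene names or aliases.
#' @param annotation a [genome_annotation].
#' @return character vector of canonical gene names covered by the span.
#' @export
expand_deletion_span <- function(flank_a, flank_b, annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  a <- resolve_gene(flank_a, annotation)
  b <- resolve_gene(flank_b, annotation)
  g <- annotation$genes
  ia <- match(a, g$name)
  ib <- match(b, g$name)
  g$name[seq(min(ia, ib), max(ia, ib))]
}

strip_is_tag <- function(site) sub(paste0(IS_SEPARATOR, ".*$"), "", site)

is_intergenic_site <- function(site) grepl("-", strip_is_tag(site), fixed = TRUE)

#' Genomic length of a site
#'
#' For a gene the length is `end - start + 1`; for an intergenic site
#' `flankA-flankB` it is the gap between the flanks (at least 1 base); IS
#' tags are ignored. Used as sampling weight in the length-proportional null.
#'
#' @param sites character vector of canonical site names.
#' @param annotation a [genome_annotation].
#' @return numeric vector of lengths in bases.
#' @export
site_lengths <- function(sites, annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  g <- annotation$genes
  vapply(strip_is_tag(sites), function(s) {
    if (grepl("-", s, fixed = TRUE)) {
      fl <- strsplit(s, "-", fixed = TRUE)[[1]]
      ia <- match(fl[1], g$name); ib <- match(fl[2], g$name)
      if (is.na(ia) || is.na(ib)) stopf("intergenic flank not in annotation: '%s'", s)
      lo <- min(ia, ib); hi <- max(ia, ib)
      max(g$start[hi] - g$end[lo] - 1, 1)
    } else {
      i <- match(s, g$name)
      if (is.na(i)) stopf("site not in annotation: '%s'", s)
      g$end[i] - g$start[i] + 1
    }
  }, numeric(1), USE.NAMES = FALSE)
}
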