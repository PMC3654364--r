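#' Read a homolog (ortholog) group table
#'
#' KO-style group membership: a tab-separated file with columns
#' `group_id`, `species_id`, `protein_id` (no header; `#` comments allowed).
#' Within a group each protein is listed under exactly one species; a protein
#' may belong to several groups. Duplicate rows are dropped with a warning.
#'
#' @param path Path to the TSV file.
#' @return A `homolog_groups` tibble with columns `group_id`, `species_id`,
#'   `protein_id`, in file order per group.
#' @export
read_homolog_groups <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 3L)
  if (length(bad) > 0L) {
    stop_parse(path, keep[bad[1L]],
               sprintf("expected 3 tab-separated fields (group, species, protein), found %d",
                       nf[bad[1L]]))
  }
  tbl <- tibble::tibble(
    group_id   = vapply(parts, `[[`, "", 1L),
    species_id = vapply(parts, `[[`, "", 2L),
    protein_id = vapply(parts, `[[`, "", 3L))
  dup <- duplicated(tbl)
  if (any(dup)) {
    warning(sprintf("%d duplicate (group, species, protein) rows dropped",
                    sum(dup)), call. = FALSE)
    tbl <- tbl[!dup, ]
  }
  homolog_groups(tbl)
}

#' Construct a homolog group table from a data frame
#'
#' @param x Data frame with columns `group_id`, `species_id`, `protein_id`.
#' @return A `homolog_groups` tibble.
#' @export
homolog_groups <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("group_id", "species_id", "protein_id")
  if (!all(need %in% names(x))) {
    stop("homolog table needs columns group_id, species_id, protein_id",
         call. = FALSE)
  }
  # a protein never appears under two species within the same group
  chk <- dplyr::distinct(x, .data$group_id, .data$species_id, .data$protein_id)
  clash <- dplyr::count(chk, .data$group_id, .data$protein_id)
  multi <- dplyr::distinct(chk, .data$group_id, .data$protein_id,
                           .data$species_id)
  multi <- dplyr::count(multi, .data$group_id, .data$protein_id)
  if (any(multi$n > 1L)) {
    off <- multi[multi$n > 1L, ][1L, ]
    stop(sprintf("protein %s listed under multiple species in group %s",
                 off$protein_id, off$group_id), call. = FALSE)
  }
  class(x) <- c("homolog_groups", class(tibble::tibble()))
  x
}

#' Read all-against-all BLAST hits (tabular)
#'
#' Accepts BLAST `outfmt 6` (12+ columns; query, subject, e-value, bit score
#' taken from columns 1, 2, 11, 12) or a minimal four-column dialect
#' `query<TAB>subject<TAB>evalue<TAB>bitscore`. The best (smallest e-value)
#' record is kept per ordered pair; reported e-values of 0 are floored so
#' that downstream ratios stay finite.
#'
#' @param path Path to the tabular file.
#' @param evalue_floor Value substituted for a reported e-value of zero.
#' @return A `similarity_table` tibble with columns `query`, `subject`,
#'   `e_value`, `bit_score`, one row per ordered pair.
#' @export
read_blast_tabular <- function(path, evalue_floor = 1e-180) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 4L & nf < 12L)
  if (length(bad) > 0L) {
    stop_parse(path, keep[bad[1L]],
               "expected 4 columns (query, subject, evalue, bitscore) or >= 12 (outfmt 6)")
  }
  if (length(keep) == 0L) {
    return(similarity_table(tibble::tibble(
      query = character(), subject = character(),
      e_value = double(), bit_score = double())))
  }
  ecol <- ifelse(nf == 4L, 3L, 11L)
  bcol <- ifelse(nf == 4L, 4L, 12L)
  pick <- function(p, i) p[[i]]
  ev <- suppressWarnings(as.double(mapply(pick, parts, ecol)))
  bs <- suppressWarnings(as.double(mapply(pick, parts, bcol)))
  if (anyNA(ev)) {
    stop_parse(path, keep[which(is.na(ev))[1L]], "non-numeric e-value")
  }
  if (any(ev < 0)) {
    stop_parse(path, keep[which(ev < 0)[1L]], "negative e-value")
  }
  tbl <- tibble::tibble(
    query = vapply(parts, `[[`, "", 1L),
    subject = vapply(parts, `[[`, "", 2L),
    e_value = pmax(ev, evalue_floor),
    bit_score = bs)
  similarity_table(tbl)
}

#' Construct a similarity table from a data frame
#'
#' Keeps the best (smallest e-value, ties by larger bit score) record per
#' ordered (query, subject) pair.
#'
#' @param x Data frame with columns `query`, `subject`, `e_value`,
#'   `bit_score`.
#' @return A `similarity_table` tibble.
#' @export
similarity_table <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("query", "subject", "e_value", "bit_score")
  if (!all(need %in% names(x))) {
    stop("similarity table needs columns query, subject, e_value, bit_score",
         call. = FALSE)
  }
  if (nrow(x) > 0L && any(x$e_value <= 0)) {
    stop("e-values must be positive (floor zeros before construction)",
         call. = FALSE)
  }
  x <- dplyr::arrange(x, .data$query, .data$subject, .data$e_value,
                      dplyr::desc(.data$bit_score))
  x <- dplyr::distinct(x, .data$query, .data$subject, .keep_all = TRUE)
  class(x) <- c("similarity_table", class(tibble::tibble()))
  x
}

#' Look up cross-species e-values for protein pairs
#'
#' The pair is treated as unordered: the smaller e-value of the two stored
#' directions is returned. A missing pair is a distinct outcome (`NA`), not
#' zero.
#'
#' @param similarity A [similarity_table()].
#' @param a,b Character vectors of protein ids (recycled to common length).
#' @return Numeric vector of e-values, `NA` where the pair is absent.
#' @export
similarity_evalue <- function(similarity, a, b) {
  key <- paste(similarity$query, similarity$subject, sep = "\r")
  fwd <- similarity$e_value[match(paste(a, b, sep = "\r"), key)]
  rev <- similarity$e_value[match(paste(b, a, sep = "\r"), key)]
  pmin(fwd, rev, na.rm = TRUE)
}

ANNOTATION_NAMESPACES <- c("GO_BP", "KO", "MIPS_COMPLEX", "MIPS_FUNCAT")

#' Construct an annotation map
#'
#' @param x Data frame with columns `protein_id`, `term_id`.
#' @param namespace One of `"GO_BP"`, `"KO"`, `"MIPS_COMPLEX"`,
#'   `"MIPS_FUNCAT"`; fixed per instance.
#' @return An `annotation_map` tibble (attribute `namespace`).
#' @export
annotation_map <- function(x, namespace) {
  namespace <- match.arg(namespace, ANNOTATION_NAMESPACES)
  x <- tibble::as_tibble(x)
  if (!all(c("protein_id", "term_id") %in% names(x))) {
    stop("annotation map needs columns protein_id, term_id", call. = FALSE)
  }
  x <- dplyr::distinct(x, .data$protein_id, .data$term_id)
  attr(x, "namespace") <- namespace
  class(x) <- c("annotation_map", class(tibble::tibble()))
  x
}

annotation_namespace <- function(x) attr(x, "namespace")

#' Read protein-to-term annotations
#'
#' Either a two-column TSV (`protein_id<TAB>term_id`) or a GAF 2.x subset
#' (`!` comment lines; DB object id in column 2, term id in column 5, aspect
#' in column 9). For the GAF dialect with namespace `GO_BP`, only aspect-P
#' rows are retained.
#'
#' @param path Path to the annotation file.
#' @param namespace Annotation namespace (see [annotation_map()]).
#' @param dialect `"tsv"` or `"gaf"`.
#' @return An `annotation_map` tibble.
#' @export
read_annotations <- function(path, namespace, dialect = c("tsv", "gaf")) {
  dialect <- match.arg(dialect)
  namespace <- match.arg(namespace, ANNOTATION_NAMESPACES)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "tsv") {
    keep <- which(!grepl("^\\s*(#|$)", lines))
    parts <- strsplit(lines[keep], "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 2L)
    if (length(bad) > 0L) {
      stop_parse(path, keep[bad[1L]], "expected 2 tab-separated fields")
    }
    tbl <- tibble::tibble(
      protein_id = vapply(parts, `[[`, "", 1L),
      term_id = vapply(parts, `[[`, "", 2L))
  } else {
    keep <- which(!grepl("^\\s*(!|$)", lines))
    parts <- strsplit(lines[keep], "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 9L)
    if (length(bad) > 0L) {
      stop_parse(path, keep[bad[1L]], "GAF line with fewer than 9 columns")
    }
    tbl <- tibble::tibble(
      protein_id = vapply(parts, `[[`, "", 2L),
      term_id = vapply(parts, `[[`, "", 5L),
      aspect = vapply(parts, `[[`, "", 9L))
    if (namespace == "GO_BP") {
      tbl <- dplyr::filter(tbl, .data$aspect == "P")
    }
    tbl <- dplyr::select(tbl, "protein_id", "term_id")
  }
  annotation_map(tbl, namespace)
}

#' Terms annotated to a set of proteins
#'
#' @param annotations An [annotation_map()].
#' @param proteins Character vector of protein ids.
#' @return Named list of character vectors (one per protein; possibly empty).
#' @export
annotation_terms <- function(annotations, proteins) {
  hits <- annotations[annotations$protein_id %in% proteins, ]
  sets <- split(hits$term_id, hits$protein_id)
  out <- stats::setNames(vector("list", length(proteins)), proteins)
  for (p in proteins) out[[p]] <- sets[[p]] %||% character()
  out
}
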