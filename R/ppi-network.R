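#' Construct a single-species PPI network
#'
#' A PPI network is an undirected graph over protein identifiers: edges are
#' stored canonically (unordered endpoints, deduplicated), optionally carrying
#' an interaction-probability weight in \[0, 1\]. Self-interactions are kept
#' but flagged; downstream alignment ignores them.
#'
#' @param edges A data frame whose first two columns are protein identifiers
#'   (character) and whose optional third column `weight` holds interaction
#'   probabilities in \[0, 1\].
#' @param species_id Species label attached to the network.
#' @param proteins Optional character vector of the protein universe; defaults
#'   to the union of edge endpoints. Isolated proteins may be added here.
#'
#' @return A `ppi_network`: a list with `species_id`, `proteins`, and an
#'   `edges` tibble with columns `from`, `to` (canonical `from <= to`),
#'   `weight`, and `self_loop`.
#' @export
ppi_network <- function(edges, species_id, proteins = NULL) {
  stopifnot(is.character(species_id), length(species_id) == 1L)
  edges <- tibble::as_tibble(edges)
  if (ncol(edges) < 2L && nrow(edges) > 0L) {
    stop("`edges` needs at least two columns of protein ids", call. = FALSE)
  }
  if (nrow(edges) == 0L) {
    edges <- tibble::tibble(from = character(), to = character(),
                            weight = double(), self_loop = logical())
  } else {
    a <- as.character(edges[[1L]])
    b <- as.character(edges[[2L]])
    w <- if ("weight" %in% names(edges)) {
      as.double(edges[["weight"]])
    } else if (ncol(edges) >= 3L && is.numeric(edges[[3L]])) {
      as.double(edges[[3L]])
    } else {
      rep(NA_real_, length(a))
    }
    bad_w <- which(!is.na(w) & (w < 0 | w > 1))
    if (length(bad_w) > 0L) {
      stop(sprintf("edge weight outside [0, 1] (first offender: %g)",
                   w[bad_w[1L]]), call. = FALSE)
    }
    edges <- tibble::tibble(from = pmin(a, b), to = pmax(a, b), weight = w,
                            self_loop = a == b)
    edges <- dplyr::arrange(
      dplyr::distinct(edges, .data$from, .data$to, .keep_all = TRUE),
      .data$from, .data$to)
  }
  proteins <- sort(unique(c(proteins, edges$from, edges$to)))
  structure(
    list(species_id = species_id, proteins = proteins, edges = edges),
    class = "ppi_network")
}

#' Read a PPI network from a tab-separated edge list
#'
#' Accepts the two-column dialect (`protein_a<TAB>protein_b`) or the
#' three-column weighted dialect with an interaction probability in \[0, 1\]
#' as the third field. Lines starting with `#` and blank lines are skipped.
#' Duplicate and reversed duplicate lines collapse to one undirected edge.
#'
#' @param path Path to the edge-list file.
#' @param species_id Species label for the network.
#' @param dialect `"tsv2col"` or `"tsv3col_weighted"`.
#' @param weight_cutoff If non-`NULL` and the dialect is weighted, edges with
#'   weight below the cutoff are dropped at load time (the conventional
#'   interaction-probability cutoff is 0.5).
#'
#' @return A [ppi_network()].
#' @export
read_ppi_network <- function(path, species_id,
                             dialect = c("tsv2col", "tsv3col_weighted"),
                             weight_cutoff = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  want <- if (dialect == "tsv2col") 2L else 3L
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != want)
  if (length(bad) > 0L) {
    stop_parse(path, keep[bad[1L]],
               sprintf("expected %d tab-separated fields, found %d",
                       want, nf[bad[1L]]))
  }
  if (length(keep) == 0L) {
    return(ppi_network(tibble::tibble(from = character(), to = character()),
                       species_id))
  }
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  if (want == 3L) {
    w <- suppressWarnings(as.double(vapply(parts, `[[`, "", 3L)))
    nonnum <- which(is.na(w))
    if (length(nonnum) > 0L) {
      stop_parse(path, keep[nonnum[1L]], "non-numeric weight")
    }
    outside <- which(w < 0 | w > 1)
    if (length(outside) > 0L) {
      stop_parse(path, keep[outside[1L]],
                 sprintf("weight %g outside [0, 1]", w[outside[1L]]))
    }
    df <- tibble::tibble(from = a, to = b, weight = w)
    if (!is.null(weight_cutoff)) {
      df <- dplyr::filter(df, .data$weight >= weight_cutoff)
    }
  } else {
    df <- tibble::tibble(from = a, to = b)
  }
  ppi_network(df, species_id)
}

#' @export
print.ppi_network <- function(x, ...) {
  n_self <- sum(x$edges$self_loop)
  cat(sprintf("<ppi_network> species %s: %d proteins, %d edges%s\n",
              x$species_id, length(x$proteins),
              nrow(x$edges) - n_self,
              if (n_self > 0L) sprintf(" (+%d self-loops)", n_self) else ""))
  invisible(x)
}

# Interaction edges usable for alignment: self-loops excluded.
network_edges <- function(net) {
  dplyr::filter(net$edges, !.data$self_loop)
}

# Fast membership test for unordered pairs of a network.
network_edge_keys <- function(net) {
  e <- network_edges(net)
  edge_key(e$from, e$to)
}
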