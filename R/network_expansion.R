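#' Load a pathway database snapshot
#'
#' Reads pathway membership from a GMT file (one pathway per line:
#' `id<TAB>description<TAB>member1<TAB>member2...`) or a long-format
#' two-column TSV (`pathway_id<TAB>gene`, with an optional third `name`
#' column). Member order is discarded; duplicate members within a pathway
#' are collapsed.
#'
#' @param path Path to the pathway file.
#' @param format Either `"gmt"` (default) or `"tsv"`.
#' @return A data frame with one row per pathway and columns `pathway_id`,
#'   `name`, and `members` (a list column of character vectors).
#' @export
load_pathway_db <- function(path, format = c("gmt", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("pathway file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (format == "gmt") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(fields, length, 0L) < 3L)
    if (length(bad)) {
      stop("malformed GMT line ", bad[1],
           ": expected at least id, description and one member")
    }
    ids <- vapply(fields, `[[`, "", 1L)
    names_ <- vapply(fields, `[[`, "", 2L)
    members <- lapply(fields, function(f) sort(unique(f[-(1:2)])))
  } else {
    df <- utils::read.delim(path, header = TRUE, colClasses = "character")
    if (ncol(df) < 2L) stop("pathway TSV needs at least 2 columns (pathway_id, gene)")
    empty <- which(!nzchar(df[[2]]))
    if (length(empty)) stop("malformed TSV line ", empty[1] + 1L, ": empty gene field")
    ids <- unique(df[[1]])
    members <- lapply(ids, function(i) sort(unique(df[[2]][df[[1]] == i])))
    names_ <- if (ncol(df) >= 3L) {
      vapply(ids, function(i) df[[3]][df[[1]] == i][1], "")
    } else ids
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate pathway_id: ", paste(unique(dup), collapse = ", "))
  no_members <- which(vapply(members, length, 0L) == 0L)
  if (length(no_members)) stop("pathway with no members at line ", no_members[1])
  out <- data.frame(pathway_id = ids, name = names_, stringsAsFactors = FALSE)
  out$members <- members
  out
}

#' Load a protein-protein interaction edge list
#'
#' Accepts SIF (`a<TAB>interaction<TAB>b`) or a plain two-column TSV.
#' Edges are undirected: `(a, b)` and `(b, a)` are collapsed. Self-loops
#' are kept but flagged; they never create focal genes on their own.
#'
#' @param path Path to the edge file.
#' @return Data frame with columns `a`, `b`, `source`, `self_loop`.
#' @export
load_ppi <- function(path) {
  if (!file.exists(path)) stop("PPI file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(a = character(), b = character(), source = character(),
                      self_loop = logical(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 0L)
  if (any(nf < 2L)) stop("malformed edge line ", which(nf < 2L)[1])
  three <- all(nf >= 3L)
  a <- vapply(fields, `[[`, "", 1L)
  b <- if (three) vapply(fields, `[[`, "", 3L) else vapply(fields, `[[`, "", 2L)
  src <- if (three) vapply(fields, `[[`, "", 2L) else "ppi"
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  keep <- !duplicated(paste(lo, hi, sep = "\r"))
  data.frame(a = lo[keep], b = hi[keep],
             source = rep_len(src, length(a))[keep],
             self_loop = (lo == hi)[keep], stringsAsFactors = FALSE)
}

#' Load a two-column alias table (accession -> gene symbol)
#'
#' @param path TSV with columns alias, symbol (header optional but expected).
#' @return Named character vector mapping alias to symbol.
#' @export
load_aliases <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (ncol(df) < 2L) stop("alias table needs 2 columns (alias, symbol)")
  map <- df[[2]]
  names(map) <- df[[1]]
  clash <- tapply(map, names(map), function(x) length(unique(x)))
  if (any(clash > 1L)) {
    stop("alias maps to multiple symbols: ",
         paste(names(clash)[clash > 1L], collapse = ", "))
  }
  map[!duplicated(names(map))]
}

#' Resolve query identifiers through an alias table
#'
#' Identifiers already present as symbols pass through; others are looked up
#' in the alias map. Unresolvable identifiers are reported in the
#' `unresolved` attribute, not silently dropped.
#'
#' @param queries Character vector of gene symbols and/or accessions.
#' @param aliases Named character vector from [load_aliases()], or `NULL`.
#' @return Character vector of symbols with attribute `unresolved`.
#' @export
resolve_queries <- function(queries, aliases = NULL) {
  hit <- if (is.null(aliases)) rep(NA_character_, length(queries)) else
    unname(aliases[queries])
  out <- ifelse(is.na(hit), queries, hit)
  attr(out, "unresolved") <- character(0)
  if (!is.null(aliases)) {
    # an identifier that looks like an accession (present nowhere) is kept
    # as-is; callers can inspect `unresolved` to warn
    attr(out, "unresolved") <- queries[is.na(hit) & !(queries %in% aliases)]
  }
  out
}

focal_frame <- function(gene, is_query, sources, via) {
  data.frame(gene = gene, is_query = is_query, sources = sources, via = via,
             stringsAsFactors = FALSE)
}

#' Expand query genes to their focal-gene set
#'
#' A gene is focal when it shares at least one pathway with a query gene or
#' its protein has a direct interaction edge to a query gene's protein.
#' Query genes are always included and flagged `is_query`; queries absent
#' from every snapshot come back with empty provenance, mirroring the case
#' where a risk gene is simply not present in the databases.
#'
#' @param queries Character vector of query gene symbols (non-empty).
#' @param pathways Data frame from [load_pathway_db()].
#' @param edges Data frame from [load_ppi()].
#' @return Data frame ordered lexicographically by `gene` with columns
#'   `gene`, `is_query`, `sources` (semicolon-joined subset of
#'   `pathway`/`ppi`) and `via` (semicolon-joined pathway ids / query genes).
#' @export
expand_from_proteins <- function(queries, pathways, edges) {
  queries <- unique(as.character(queries))
  if (!length(queries)) stop("queries must be non-empty")
  prov <- list()   # gene -> list(sources = chr, via = chr)
  add <- function(gene, source, via) {
    cur <- prov[[gene]]
    if (is.null(cur)) cur <- list(sources = character(), via = character())
    cur$sources <- union(cur$sources, source)
    cur$via <- union(cur$via, via)
    prov[[gene]] <<- cur
  }
  if (nrow(pathways)) {
    for (i in seq_len(nrow(pathways))) {
      mem <- pathways$members[[i]]
      hit_q <- intersect(queries, mem)
      if (!length(hit_q)) next
      for (g in mem) {
        # a gene is pathway-focal iff it co-occurs with a query other than
        # itself; a query gene can be pathway-focal of another query
        if (length(setdiff(hit_q, g))) add(g, "pathway", pathways$pathway_id[i])
      }
    }
  }
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      if (edges$self_loop[i]) next
      a <- edges$a[i]; b <- edges$b[i]
      if (a %in% queries) add(b, "ppi", a)
      if (b %in% queries) add(a, "ppi", b)
    }
  }
  genes <- sort(unique(c(queries, names(prov))))
  focal_frame(
    gene = genes,
    is_query = genes %in% queries,
    sources = vapply(genes, function(g) {
      p <- prov[[g]]
      if (is.null(p)) "" else paste(sort(p$sources), collapse = ";")
    }, ""),
    via = vapply(genes, function(g) {
      p <- prov[[g]]
      if (is.null(p)) "" else paste(sort(p$via), collapse = ";")
    }, "")
  )
}

#' Expand pathway names to their member genes
#'
#' Matching is exact but case-insensitive against both pathway id and name.
#'
#' @param names_ Character vector of pathway names or ids (non-empty).
#' @param pathways Data frame from [load_pathway_db()].
#' @return Focal-gene data frame (all `provenance = pathway`); a warning is
#'   raised when no pathway matches and an empty frame returned.
#' @export
expand_from_pathways <- function(names_, pathways) {
  if (!length(names_)) stop("names must be non-empty")
  want <- tolower(names_)
  hit <- tolower(pathways$pathway_id) %in% want | tolower(pathways$name) %in% want
  if (!any(hit)) {
    warning("no pathway matched: ", paste(names_, collapse = ", "))
    return(focal_frame(character(), logical(), character(), character()))
  }
  via <- list()
  for (i in which(hit)) {
    for (g in pathways$members[[i]]) {
      via[[g]] <- union(via[[g]], pathways$pathway_id[i])
    }
  }
  genes <- sort(names(via))
  focal_frame(genes, FALSE, rep("pathway", length(genes)),
              vapply(genes, function(g) paste(sort(via[[g]]), collapse = ";"), ""))
}

#' Tabulate focal genes by database source combination
#'
#' Counts non-query focal genes per provenance subset (`pathway` only,
#' `ppi` only, `both`), the breakdown behind source-distribution summaries.
#'
#' @param focal Focal-gene data frame.
#' @return Named integer vector `c(pathway = , ppi = , both = )`.
#' @export
source_distribution <- function(focal) {
  out <- c(pathway = 0L, ppi = 0L, both = 0L)
  if (!nrow(focal)) return(out)
  nonq <- focal[!focal$is_query & nzchar(focal$sources), , drop = FALSE]
  if (!nrow(nonq)) return(out)
  both <- grepl("pathway", nonq$sources) & grepl("ppi", nonq$sources)
  out["both"] <- sum(both)
  out["pathway"] <- sum(grepl("pathway", nonq$sources) & !both)
  out["ppi"] <- sum(grepl("ppi", nonq$sources) & !both)
  out
}
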