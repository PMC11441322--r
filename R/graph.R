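#' Construct a property graph from node and edge tables
#'
#' An in-memory SPOKE-style property graph: typed, named nodes and directed,
#' attributed edges whose predicates follow the upper/lower initial schema
#' (see [parse_predicate()]). Edges carry provenance (source database names),
#' optional statistical evidence (p-value and/or z-score), an optional
#' clinical phase (treatment edges) and an optional source type (e.g.
#' `"textmining"` vs `"curated"`).
#'
#' Validation is strict at construction time: node ids must be unique, node
#' types and names non-empty, every edge endpoint must resolve to a node, and
#' every predicate must parse under the schema with its two type initials
#' matching the endpoint node types' first letters (case-insensitively).
#'
#' @param nodes A data frame with columns `node_id`, `node_type`, `name`,
#'   and optionally `identifier` and `attributes` (a list column of named
#'   lists; `attributes$curated` marks curated Protein nodes).
#' @param edges A data frame with columns `subject_id`, `predicate`,
#'   `object_id`, and optionally `provenance` (list of character vectors),
#'   `evidence` (list of named lists with `p_value`/`z_score`),
#'   `clinical_phase` (integer 0-4 or `NA`), `source_type` (character or
#'   `NA`).
#' @param abbreviations Optional node-type abbreviation table passed to
#'   [parse_predicate()].
#' @return An object of class `kg_graph`: a list with tibbles `nodes` and
#'   `edges` plus lookup indexes by node id, by `(node_type, lower-cased
#'   NFC-normalized name)`, and by incident node.
#' @examples
#' g <- kg_graph(
#'   nodes = tibble::tibble(
#'     node_id = c("d1", "g1"),
#'     node_type = c("Disease", "Gene"),
#'     name = c("hypertension", "VHL")
#'   ),
#'   edges = tibble::tibble(
#'     subject_id = "d1", predicate = "ASSOCIATES_DaG", object_id = "g1"
#'   )
#' )
#' g
#' @export
kg_graph <- function(nodes, edges, abbreviations = NULL) {
  nodes <- normalize_nodes(nodes)
  edges <- normalize_edges(edges)

  dup <- nodes$node_id[duplicated(nodes$node_id)]
  if (length(dup) > 0) {
    abort(sprintf(
      "Duplicate node_id(s): %s.",
      paste(encodeString(unique(dup), quote = '"'), collapse = ", ")
    ), class = "kgrag_load_error")
  }
  if (any(!nzchar(nodes$node_type)) || anyNA(nodes$node_type)) {
    abort("Every node must have a non-empty node_type.", class = "kgrag_load_error")
  }
  if (any(!nzchar(nodes$name)) || anyNA(nodes$name)) {
    abort("Every node must have a non-empty name.", class = "kgrag_load_error")
  }

  if (nrow(edges) > 0) {
    missing_sub <- !(edges$subject_id %in% nodes$node_id)
    missing_obj <- !(edges$object_id %in% nodes$node_id)
    if (any(missing_sub | missing_obj)) {
      i <- which(missing_sub | missing_obj)[1]
      bad <- if (missing_sub[i]) edges$subject_id[i] else edges$object_id[i]
      abort(sprintf(
        "Edge %d (%s -[%s]-> %s) references unknown node id %s.",
        i, encodeString(edges$subject_id[i], quote = '"'), edges$predicate[i],
        encodeString(edges$object_id[i], quote = '"'),
        encodeString(bad, quote = '"')
      ), class = "kgrag_load_error")
    }
    parts <- parse_predicate(edges$predicate, abbreviations = abbreviations)
    type_of <- stats::setNames(nodes$node_type, nodes$node_id)
    sub_init <- type_initial(type_of[edges$subject_id], abbreviations)
    obj_init <- type_initial(type_of[edges$object_id], abbreviations)
    bad <- toupper(parts$subject_initial) != toupper(sub_init) |
      toupper(parts$object_initial) != toupper(obj_init)
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf(
        "Edge %d: predicate %s type initials do not match endpoint types %s -> %s.",
        i, encodeString(edges$predicate[i], quote = '"'),
        encodeString(type_of[edges$subject_id[i]], quote = '"'),
        encodeString(type_of[edges$object_id[i]], quote = '"')
      ), class = "kgrag_load_error")
    }
  }

  structure(
    list(
      nodes = nodes,
      edges = edges,
      abbreviations = abbreviations,
      node_row = stats::setNames(seq_len(nrow(nodes)), nodes$node_id),
      name_index = split(
        nodes$node_id,
        paste(nodes$node_type, name_key(nodes$name), sep = "\r")
      ),
      incident = incident_index(nodes$node_id, edges)
    ),
    class = "kg_graph"
  )
}

name_key <- function(x) stringi::stri_trans_nfc(stringr::str_to_lower(x))

type_initial <- function(node_type, abbreviations = NULL) {
  init <- toupper(substr(node_type, 1, 1))
  if (!is.null(abbreviations)) {
    hit <- match(node_type, names(abbreviations))
    init[!is.na(hit)] <- abbreviations[hit[!is.na(hit)]]
  }
  init
}

normalize_nodes <- function(nodes) {
  nodes <- as_tibble(nodes)
  need <- setdiff(c("node_id", "node_type", "name"), names(nodes))
  if (length(need) > 0) {
    abort(sprintf("Node table is missing column(s): %s.", paste(need, collapse = ", ")),
      class = "kgrag_load_error")
  }
  if (!"identifier" %in% names(nodes)) nodes$identifier <- NA_character_
  if (!"attributes" %in% names(nodes)) {
    nodes$attributes <- rep(list(list()), nrow(nodes))
  } else if (!is.list(nodes$attributes)) {
    abort("`attributes` must be a list column of named lists.", class = "kgrag_load_error")
  }
  nodes$node_id <- as.character(nodes$node_id)
  nodes$node_type <- as.character(nodes$node_type)
  nodes$name <- as.character(nodes$name)
  nodes$identifier <- as.character(nodes$identifier)
  nodes$attributes <- map(nodes$attributes, function(a) if (is.null(a)) list() else as.list(a))
  nodes[c("node_id", "node_type", "name", "identifier", "attributes")]
}

normalize_edges <- function(edges) {
  edges <- as_tibble(edges)
  need <- setdiff(c("subject_id", "predicate", "object_id"), names(edges))
  if (length(need) > 0) {
    abort(sprintf("Edge table is missing column(s): %s.", paste(need, collapse = ", ")),
      class = "kgrag_load_error")
  }
  n <- nrow(edges)
  if (!"provenance" %in% names(edges)) edges$provenance <- rep(list(character()), n)
  if (!"evidence" %in% names(edges)) edges$evidence <- rep(list(NULL), n)
  if (!"clinical_phase" %in% names(edges)) edges$clinical_phase <- NA_integer_
  if (!"source_type" %in% names(edges)) edges$source_type <- NA_character_
  edges$subject_id <- as.character(edges$subject_id)
  edges$predicate <- as.character(edges$predicate)
  edges$object_id <- as.character(edges$object_id)
  edges$provenance <- map(edges$provenance, function(p) {
    if (is.null(p) || all(is.na(p))) character() else as.character(p)
  })
  edges$evidence <- map(edges$evidence, function(e) {
    if (is.null(e) || length(e) == 0) return(NULL)
    e <- as.list(e)
    keep <- intersect(names(e), c("p_value", "z_score"))
    e <- e[keep]
    e <- e[!map_lgl(e, function(v) is.null(v) || all(is.na(v)))]
    if (length(e) == 0) NULL else map(e, as.numeric)
  })
  edges$clinical_phase <- as.integer(edges$clinical_phase)
  bad_phase <- !is.na(edges$clinical_phase) &
    (edges$clinical_phase < 0L | edges$clinical_phase > 4L)
  if (any(bad_phase)) {
    abort("`clinical_phase` must be an integer in 0-4 (or missing).",
      class = "kgrag_load_error")
  }
  edges$source_type <- as.character(edges$source_type)
  edges[c("subject_id", "predicate", "object_id", "provenance", "evidence",
          "clinical_phase", "source_type")]
}

incident_index <- function(node_ids, edges) {
  idx <- new.env(parent = emptyenv(), size = max(16L, length(node_ids)))
  if (nrow(edges) > 0) {
    both <- c(edges$subject_id, edges$object_id)
    rows <- rep(seq_len(nrow(edges)), 2L)
    sp <- split(rows, both)
    for (id in names(sp)) assign(id, sort(unique(sp[[id]])), envir = idx)
  }
  idx
}

#' @export
print.kg_graph <- function(x, ...) {
  cat(sprintf(
    "<kg_graph> %d nodes (%d types), %d edges (%d predicates)\n",
    nrow(x$nodes), dplyr::n_distinct(x$nodes$node_type),
    nrow(x$edges), dplyr::n_distinct(x$edges$predicate)
  ))
  invisible(x)
}

#' @export
format.kg_graph <- function(x, ...) {
  sprintf("<kg_graph> %d nodes, %d edges", nrow(x$nodes), nrow(x$edges))
}

#' Load a property graph from node and edge files
#'
#' Reads the tabular on-disk representation: a nodes table with columns
#' `node_id`, `node_type`, `name`, `identifier`, `attributes` (JSON object)
#' and an edges table with columns `subject_id`, `predicate`, `object_id`,
#' `provenance` (JSON array), `evidence` (JSON object or empty),
#' `clinical_phase` (integer or empty), `source_type`. Both TSV (one header
#' row) and JSONL (one object per line) are supported, detected from the file
#' extension or forced via `format`.
#'
#' @param nodes_path,edges_path Paths to the node and edge tables.
#' @param format `"auto"` (default; `.jsonl`/`.ndjson` files are JSONL,
#'   anything else TSV), `"tsv"` or `"jsonl"`.
#' @inheritParams kg_graph
#' @return A validated [kg_graph()].
#' @seealso [write_graph()]
#' @export
read_graph <- function(nodes_path, edges_path, format = c("auto", "tsv", "jsonl"),
                       abbreviations = NULL) {
  format <- match.arg(format)
  nodes <- read_table_file(nodes_path, format)
  edges <- read_table_file(edges_path, format)
  nodes <- decode_json_col(nodes, "attributes", default = list())
  edges <- decode_json_col(edges, "provenance", default = character())
  edges <- decode_json_col(edges, "evidence", default = NULL)
  kg_graph(nodes, edges, abbreviations = abbreviations)
}

read_table_file <- function(path, format) {
  if (format == "auto") {
    format <- if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) "jsonl" else "tsv"
  }
  if (format == "jsonl") {
    lines <- readr::read_lines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) return(tibble())
    rows <- map(lines, function(l) jsonlite::fromJSON(l, simplifyVector = FALSE))
    cols <- unique(unlist(map(rows, names)))
    out <- map(cols, function(col) {
      vals <- map(rows, function(r) r[[col]])
      if (col %in% c("provenance", "evidence", "attributes")) {
        map(vals, function(v) if (is.null(v)) NULL else v)
      } else {
        map_chr(vals, function(v) if (is.null(v)) NA_character_ else as.character(v))
      }
    })
    tibble::new_tibble(stats::setNames(out, cols), nrow = length(rows))
  } else {
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE, show_col_types = FALSE)
  }
}

decode_json_col <- function(df, col, default) {
  if (!col %in% names(df)) return(df)
  if (is.list(df[[col]])) {
    df[[col]] <- map(df[[col]], function(v) {
      if (is.null(v)) default else v
    })
    return(df)
  }
  df[[col]] <- map(df[[col]], function(s) {
    if (is.na(s) || !nzchar(s)) return(default)
    jsonlite::fromJSON(s, simplifyVector = TRUE)
  })
  df
}

#' Write a property graph to node and edge files
#'
#' Serializes a graph to the same tabular layout [read_graph()] consumes;
#' `read_graph(write_graph(...))` is the identity on node and edge multisets.
#'
#' @param graph A [kg_graph()].
#' @param nodes_path,edges_path Output paths.
#' @param format `"tsv"` (default) or `"jsonl"`.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_graph <- function(graph, nodes_path, edges_path, format = c("tsv", "jsonl")) {
  stopifnot(inherits(graph, "kg_graph"))
  format <- match.arg(format)
  nodes <- graph$nodes
  edges <- graph$edges
  to_json <- function(x) {
    if (is.null(x) || length(x) == 0) "" else
      as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  }
  if (format == "tsv") {
    nodes_out <- nodes |>
      mutate(attributes = map_chr(.data$attributes, to_json))
    edges_out <- edges |>
      mutate(
        provenance = map_chr(.data$provenance, function(p) {
          as.character(jsonlite::toJSON(as.character(p)))
        }),
        evidence = map_chr(.data$evidence, to_json)
      )
    # fields are JSON or plain ids with no tabs/newlines; escaping would
    # corrupt the embedded quotes on re-read
    readr::write_tsv(nodes_out, nodes_path, progress = FALSE, escape = "none")
    readr::write_tsv(edges_out, edges_path, progress = FALSE, escape = "none")
  } else {
    write_jsonl <- function(df, path) {
      lines <- map_chr(seq_len(nrow(df)), function(i) {
        row <- as.list(df[i, ])
        row <- map(row, function(v) if (is.list(v)) v[[1]] else v)
        row <- row[!map_lgl(row, function(v) is.null(v) || (length(v) == 1 && is.na(v)))]
        as.character(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA, null = "null"))
      })
      readr::write_lines(lines, path)
    }
    write_jsonl(nodes, nodes_path)
    write_jsonl(edges, edges_path)
  }
  invisible(c(nodes_path, edges_path))
}

#' Quality filters applied to a disease neighborhood
#'
#' The default settings reproduce the quality filters used when pulling
#' disease context out of a SPOKE-style graph: treatment edges are kept only
#' at clinical phase 3 or higher, Protein neighbors must be curated
#' (SwissProt-style), and text-mining-derived Disease-Gene associations are
#' excluded.
#'
#' `clinical_phase` filtering only applies to edges that carry the attribute;
#' edges without a phase are unaffected.
#'
#' @param min_clinical_phase Minimum clinical phase for edges carrying one.
#' @param require_curated_protein Drop triples whose neighbor is an uncurated
#'   Protein node.
#' @param exclude_textmining_disease_gene Drop Disease-Gene edges whose
#'   `source_type` is `"textmining"`.
#' @return An object of class `kg_context_filter`.
#' @export
context_filter <- function(min_clinical_phase = 3L,
                           require_curated_protein = TRUE,
                           exclude_textmining_disease_gene = TRUE) {
  stopifnot(
    is.numeric(min_clinical_phase), length(min_clinical_phase) == 1,
    is.logical(require_curated_protein), length(require_curated_protein) == 1,
    is.logical(exclude_textmining_disease_gene),
    length(exclude_textmining_disease_gene) == 1
  )
  structure(
    list(
      min_clinical_phase = as.integer(min_clinical_phase),
      require_curated_protein = require_curated_protein,
      exclude_textmining_disease_gene = exclude_textmining_disease_gene
    ),
    class = "kg_context_filter"
  )
}

#' A filter that keeps every edge
#'
#' Convenience permissive filter: no phase floor, uncurated proteins allowed,
#' text-mining edges allowed. Useful for oracle comparisons and debugging.
#' @return A `kg_context_filter`.
#' @export
permissive_filter <- function() {
  context_filter(
    min_clinical_phase = 0L,
    require_curated_protein = FALSE,
    exclude_textmining_disease_gene = FALSE
  )
}

#' Find nodes by type and (case-insensitive) exact name
#'
#' Exact lookup against the graph's lower-cased, NFC-normalized name index.
#'
#' @param graph A [kg_graph()].
#' @param node_type Node type token, e.g. `"Disease"`.
#' @param name Node name; matching ignores case and Unicode normalization
#'   form.
#' @return A tibble of matching node records, ordered by `node_id`; empty
#'   when the type or name is absent.
#' @export
find_nodes_by_name <- function(graph, node_type, name) {
  stopifnot(inherits(graph, "kg_graph"))
  ids <- graph$name_index[[paste(node_type, name_key(name), sep = "\r")]]
  if (is.null(ids)) return(graph$nodes[0, ])
  graph$nodes[graph$node_row[sort(ids)], ]
}

#' Retrieve the filtered one-hop neighborhood of a node as attributed triples
#'
#' Returns every edge incident to `node_id` — incoming and outgoing, with the
#' stored subject/object orientation preserved — that survives the quality
#' `filter`, joined with both endpoint node records. The "neighbor" columns
#' describe the endpoint that is not `node_id` (for self-loops the node
#' itself). Output order is deterministic: by predicate, then neighbor id.
#'
#' @param graph A [kg_graph()].
#' @param node_id Id of the center node; must exist.
#' @param filter A [context_filter()]; defaults reproduce the standard
#'   quality filters.
#' @return A tibble of attributed triples with columns `subject_id`,
#'   `subject_type`, `subject_name`, `predicate`, `object_id`, `object_type`,
#'   `object_name`, `provenance`, `evidence`, `clinical_phase`,
#'   `source_type`, `neighbor_id`, `neighbor_type`, `neighbor_name`.
#' @export
neighborhood <- function(graph, node_id, filter = context_filter()) {
  stopifnot(inherits(graph, "kg_graph"), inherits(filter, "kg_context_filter"))
  if (length(node_id) != 1 || !node_id %in% graph$nodes$node_id) {
    abort(sprintf("Unknown node id %s.", encodeString(node_id, quote = '"')),
      class = "kgrag_lookup_error")
  }
  rows <- get0(node_id, envir = graph$incident, ifnotfound = integer())
  triples <- triple_table(graph, rows, center = node_id)
  if (nrow(triples) == 0) return(triples)

  keep <- rep(TRUE, nrow(triples))
  phase <- triples$clinical_phase
  keep <- keep & (is.na(phase) | phase >= filter$min_clinical_phase)
  if (filter$require_curated_protein) {
    is_protein <- triples$neighbor_type == "Protein"
    curated <- map_lgl(graph$nodes$attributes[graph$node_row[triples$neighbor_id]],
      function(a) isTRUE(as.logical(a$curated %||% FALSE)))
    keep <- keep & (!is_protein | curated)
  }
  if (filter$exclude_textmining_disease_gene) {
    dg <- (triples$subject_type == "Disease" & triples$object_type == "Gene") |
      (triples$subject_type == "Gene" & triples$object_type == "Disease")
    tm <- !is.na(triples$source_type) & triples$source_type == "textmining"
    keep <- keep & !(dg & tm)
  }
  triples <- triples[keep, ]
  triples[order(triples$predicate, triples$neighbor_id), ]
}

triple_table <- function(graph, edge_rows, center) {
  if (length(edge_rows) == 0) {
    return(tibble(
      subject_id = character(), subject_type = character(),
      subject_name = character(), predicate = character(),
      object_id = character(), object_type = character(),
      object_name = character(), provenance = list(), evidence = list(),
      clinical_phase = integer(), source_type = character(),
      neighbor_id = character(), neighbor_type = character(),
      neighbor_name = character()
    ))
  }
  edges <- graph$edges[edge_rows, ]
  sub <- graph$nodes[graph$node_row[edges$subject_id], ]
  obj <- graph$nodes[graph$node_row[edges$object_id], ]
  is_out <- edges$subject_id == center
  tibble(
    subject_id = edges$subject_id,
    subject_type = sub$node_type,
    subject_name = sub$name,
    predicate = edges$predicate,
    object_id = edges$object_id,
    object_type = obj$node_type,
    object_name = obj$name,
    provenance = edges$provenance,
    evidence = edges$evidence,
    clinical_phase = edges$clinical_phase,
    source_type = edges$source_type,
    neighbor_id = ifelse(is_out, edges$object_id, edges$subject_id),
    neighbor_type = ifelse(is_out, obj$node_type, sub$node_type),
    neighbor_name = ifelse(is_out, obj$name, sub$name)
  )
}
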