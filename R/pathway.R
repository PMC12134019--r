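#' Pathway prior specification
#'
#' A `pathway_graph` encodes the metabolic prior used by the tree search: a
#' directed acyclic graph whose nodes are genetic variants, genes, metabolites
#' and pathway concepts, with edges pointing child -> parent (variant -> gene
#' -> metabolite/concept). Concepts are defined as ancestry predicates: a
#' variant belongs to a concept iff the concept's anchor node is among its
#' ancestors. Excluded variants (Hardy-Weinberg departure, poor amplification)
#' are retained in the graph but never returned by concept queries.
#'
#' @name pathway_graph
NULL

#' Load a pathway specification from JSON or YAML
#'
#' The file must contain top-level keys `nodes`, `edges` and `concepts`.
#' Variant nodes carry the per-variant fields (`gene`, `minor_allele`,
#' `expected_maf`, `excluded`, optional `star_label` and `placeholder`).
#'
#' @param path Path to the pathway file.
#' @param format `"auto"` (by extension), `"json"` or `"yaml"`.
#' @return A validated object of class `pathway_graph` with components
#'   `nodes` (data.frame: id, kind, label), `edges` (data.frame: child,
#'   parent), `variants` (data.frame of variant definitions) and `concepts`
#'   (named list with `label` and `ancestor`).
#' @export
load_pathway <- function(path, format = c("auto", "json", "yaml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("pathway file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yaml"
  }
  raw <- if (format == "json") {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  graph <- pathway_from_list(raw)
  violations <- validate_graph(graph)
  if (length(violations) > 0L) {
    stop("invalid pathway: ", paste(violations, collapse = "; "))
  }
  graph
}

#' @keywords internal
pathway_from_list <- function(raw) {
  if (is.null(raw$nodes) || length(raw$nodes) == 0L) stop("empty pathway: no nodes")
  if (is.null(raw$edges)) stop("pathway has no 'edges' key")
  if (is.null(raw$concepts)) stop("pathway has no 'concepts' key")

  nodes <- do.call(rbind, lapply(raw$nodes, function(n) {
    data.frame(id = as.character(n$id), kind = as.character(n$kind),
               label = as.character(if (is.null(n$label)) n$id else n$label),
               stringsAsFactors = FALSE)
  }))
  vars <- Filter(function(n) identical(n$kind, "variant"), raw$nodes)
  variants <- do.call(rbind, lapply(vars, function(n) {
    data.frame(
      rsid = as.character(n$id),
      gene = as.character(if (is.null(n$gene)) NA else n$gene),
      star_label = as.character(if (is.null(n$star_label)) NA else n$star_label),
      minor_allele = as.character(if (is.null(n$minor_allele)) NA else n$minor_allele),
      expected_maf = as.numeric(if (is.null(n$expected_maf)) NA else n$expected_maf),
      excluded = isTRUE(n$excluded),
      placeholder = isTRUE(n$placeholder),
      stringsAsFactors = FALSE)
  }))
  if (is.null(variants)) {
    variants <- data.frame(rsid = character(), gene = character(),
                           star_label = character(), minor_allele = character(),
                           expected_maf = numeric(), excluded = logical(),
                           placeholder = logical(), stringsAsFactors = FALSE)
  }
  edges <- if (length(raw$edges) == 0L) {
    data.frame(child = character(), parent = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(raw$edges, function(e) {
      e <- unlist(e)
      if (length(e) != 2L) stop("edge must be a [child, parent] pair")
      data.frame(child = as.character(e[[1L]]), parent = as.character(e[[2L]]),
                 stringsAsFactors = FALSE)
    }))
  }
  concepts <- lapply(raw$concepts, function(cc) {
    list(label = as.character(if (is.null(cc$label)) NA else cc$label),
         ancestor = as.character(cc$ancestor))
  })

  structure(list(name = if (is.null(raw$name)) "pathway" else raw$name,
                 nodes = nodes, edges = edges, variants = variants,
                 concepts = concepts),
            class = "pathway_graph")
}

#' Validate a pathway graph
#'
#' Checks the structural invariants: unique node ids, no dangling edge
#' endpoints, acyclicity, every variant having at least one gene parent,
#' every gene reaching at least one concept anchor, concept ancestors
#' existing, and variant fields being in range.
#'
#' @param graph A `pathway_graph`.
#' @return Character vector of violations; empty if the graph is valid.
#' @export
validate_graph <- function(graph) {
  v <- character()
  ids <- graph$nodes$id
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) v <- c(v, paste0("duplicate id: ", dup))

  known <- ids
  dang <- unique(c(setdiff(graph$edges$child, known), setdiff(graph$edges$parent, known)))
  if (length(dang)) v <- c(v, paste0("dangling edge endpoint: ", dang))

  # cycle check via repeated leaf stripping (Kahn) on valid endpoints only
  e <- graph$edges[graph$edges$child %in% known & graph$edges$parent %in% known, ]
  active <- known
  repeat {
    has_out <- unique(e$child)
    leaves <- setdiff(active, has_out)   # nodes with no outgoing (child) role
    if (length(leaves) == 0L) break
    active <- setdiff(active, leaves)
    e <- e[!(e$parent %in% leaves) & !(e$child %in% leaves), , drop = FALSE]
    if (length(active) == 0L) break
  }
  if (length(active) > 0L && nrow(e) > 0L) {
    v <- c(v, paste0("cycle involving: ", paste(sort(unique(c(e$child, e$parent))), collapse = ",")))
  }

  kind_of <- stats::setNames(graph$nodes$kind, graph$nodes$id)
  for (rs in graph$variants$rsid) {
    par <- graph$edges$parent[graph$edges$child == rs]
    if (!any(kind_of[par] == "gene", na.rm = TRUE)) {
      v <- c(v, paste0("orphan variant (no gene parent): ", rs))
    }
  }
  anchors <- vapply(graph$concepts, function(cc) cc$ancestor, character(1))
  miss <- setdiff(anchors, known)
  if (length(miss)) v <- c(v, paste0("concept ancestor not a node: ", miss))

  genes <- graph$nodes$id[graph$nodes$kind == "gene"]
  for (g in genes) {
    anc <- node_ancestors(graph, g)
    if (!any(c(g, anc) %in% anchors)) {
      v <- c(v, paste0("gene not reachable from any concept: ", g))
    }
  }
  bad_maf <- graph$variants$rsid[!is.na(graph$variants$expected_maf) &
    (graph$variants$expected_maf < 0 | graph$variants$expected_maf > 0.5)]
  if (length(bad_maf)) v <- c(v, paste0("expected_maf outside [0, 0.5]: ", bad_maf))
  v
}

#' Transitive ancestors of a node (following child -> parent edges)
#' @keywords internal
node_ancestors <- function(graph, id) {
  seen <- character()
  frontier <- id
  while (length(frontier) > 0L) {
    nxt <- unique(graph$edges$parent[graph$edges$child %in% frontier])
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Variants mapped to a pathway concept
#'
#' Returns the rsids of all non-excluded variants whose ancestry contains the
#' concept's anchor node. Excluded variants are never returned.
#'
#' @param graph A `pathway_graph`.
#' @param concept_id Concept identifier (a name of `graph$concepts`).
#' @return Character vector of rsids (sorted).
#' @export
variants_for_concept <- function(graph, concept_id) {
  if (!concept_id %in% names(graph$concepts)) {
    stop("unknown concept id: ", concept_id)
  }
  anchor <- graph$concepts[[concept_id]]$ancestor
  keep <- graph$variants$rsid[!graph$variants$excluded]
  hits <- vapply(keep, function(rs) anchor %in% node_ancestors(graph, rs), logical(1))
  sort(keep[hits])
}

#' Analyzed (non-excluded) variants of a pathway
#' @param graph A `pathway_graph`.
#' @return Character vector of rsids in pathway-file order.
#' @export
analyzed_variants <- function(graph) {
  graph$variants$rsid[!graph$variants$excluded]
}

#' Variant -> concept membership matrix
#'
#' @param graph A `pathway_graph`.
#' @return Logical matrix, rows = analyzed variants, columns = concepts.
#' @export
concept_membership <- function(graph) {
  vars <- analyzed_variants(graph)
  cps <- names(graph$concepts)
  m <- matrix(FALSE, length(vars), length(cps), dimnames = list(vars, cps))
  for (cp in cps) m[intersect(variants_for_concept(graph, cp), vars), cp] <- TRUE
  m
}

#' Serialize a pathway graph back to JSON or YAML
#'
#' Round-trips with [load_pathway()]: load -> write -> load yields the same
#' node, edge and concept sets.
#'
#' @param graph A `pathway_graph`.
#' @param path Output path.
#' @param format `"auto"`, `"json"` or `"yaml"`.
#' @return `path`, invisibly.
#' @export
write_pathway <- function(graph, path, format = c("auto", "json", "yaml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "yaml"
  }
  vd <- graph$variants
  nodes <- lapply(seq_len(nrow(graph$nodes)), function(i) {
    n <- list(id = graph$nodes$id[i], kind = graph$nodes$kind[i],
              label = graph$nodes$label[i])
    if (n$kind == "variant") {
      j <- match(n$id, vd$rsid)
      n$gene <- vd$gene[j]
      if (!is.na(vd$star_label[j])) n$star_label <- vd$star_label[j]
      n$minor_allele <- vd$minor_allele[j]
      n$expected_maf <- vd$expected_maf[j]
      n$excluded <- vd$excluded[j]
      if (vd$placeholder[j]) n$placeholder <- TRUE
    }
    n
  })
  edges <- lapply(seq_len(nrow(graph$edges)),
                  function(i) list(graph$edges$child[i], graph$edges$parent[i]))
  out <- list(name = graph$name, nodes = nodes, edges = edges,
              concepts = graph$concepts)
  if (format == "json") {
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

#' The shipped default tamoxifen-metabolism pathway
#'
#' 26 variants in 15 genes (6 pre-excluded), 5 metabolite nodes and 10
#' concepts covering phase I/II metabolism, transport, the four active and
#' conjugated metabolites, and CYP2D6/CYP3A enzymatic activity.
#'
#' @return A `pathway_graph`.
#' @export
default_pathway <- function() {
  load_pathway(system.file("extdata", "tamoxifen_pathway.yaml",
                           package = "tampath", mustWork = TRUE))
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("pathway_graph:", x$name, "\n")
  cat(sprintf("  %d nodes (%d variants, %d excluded), %d edges, %d concepts\n",
              nrow(x$nodes), nrow(x$variants), sum(x$variants$excluded),
              nrow(x$edges), length(x$concepts)))
  invisible(x)
}
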