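#' @include AllClasses.R AllGenerics.R screen.R
NULL

# symbols of the membership head of a run: first topN probes (top_n rule) or
# the first topK distinct gene symbols (top_k rule)
runMemberSymbols <- function(run, ann, topN, membership, topK) {
  s <- run@scores
  head <- s[seq_len(min(topN, nrow(s))), , drop = FALSE]
  sym <- if (is.null(ann)) head$gene_symbol
         else unname(mapProbesToSymbols(head$probe_id, ann))
  if (membership == "top_k") sym <- unique(sym)[seq_len(min(topK,
                                                  length(unique(sym))))]
  sym
}

# gene panel of a run: distinct symbols in the topN head, each with its best
# probe and rank, excluding the run's own target gene
runGenePanel <- function(run, ann, topN) {
  s <- run@scores
  head <- s[seq_len(min(topN, nrow(s))), , drop = FALSE]
  sym <- if (is.null(ann)) head$gene_symbol
         else unname(mapProbesToSymbols(head$probe_id, ann))
  first <- !duplicated(sym)
  data.frame(gene = sym[first], probe_id = head$probe_id[first],
             rank = head$rank[first], degenerate = head$degenerate[first],
             stringsAsFactors = FALSE)
}

#' Assemble an interaction network from stored screening runs
#'
#' Pure bookkeeping over precomputed rankings (usable with injected
#' [rankedList()] objects for auditing): records a directed edge from each
#' run's seed gene to every other panel gene whose probe(s) appear in that
#' run's membership head, and counts, for every panel gene, the number of
#' runs seeded by *other* panel genes that contain it (its interconnection
#' count).
#'
#' @param runs named list of [RankedList-class] objects; names are the gene
#'   symbols the runs were seeded on.
#' @param seedGene symbol of the network's seed gene (role tag `seed`; all
#'   other run genes are tagged `panel`).
#' @param ann optional probe annotation for symbol lookup; when `NULL` the
#'   rankings' own `gene_symbol` column is used.
#' @param topN membership-head length (default 100).
#' @param membership `"top_n"` or `"top_k"` membership rule (see
#'   [GrowthConfig-class]).
#' @param topK panel size under the `"top_k"` rule.
#' @return An [InteractionNetwork-class].
#' @export
interactionNetworkFromRuns <- function(runs, seedGene, ann = NULL,
                                       topN = 100,
                                       membership = c("top_n", "top_k"),
                                       topK = 10) {
  membership <- match.arg(membership)
  stopifnot(length(runs) >= 1, !is.null(names(runs)),
            all(nzchar(names(runs))))
  genes <- names(runs)
  members <- lapply(runs, runMemberSymbols, ann = ann, topN = topN,
                    membership = membership, topK = topK)
  edges <- list()
  for (g in genes) {
    run <- runs[[g]]
    head <- run@scores[seq_len(min(topN, nrow(run@scores))), , drop = FALSE]
    sym <- if (is.null(ann)) head$gene_symbol
           else unname(mapProbesToSymbols(head$probe_id, ann))
    for (other in setdiff(genes, g)) {
      hit <- other %in% members[[g]]
      if (hit) {
        rank <- min(head$rank[sym == other])
        edges[[length(edges) + 1L]] <-
          data.frame(from = g, to = other, member_rank = rank,
                     stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(from = character(), to = character(),
                           member_rank = integer())
  counts <- vapply(genes, function(g)
    sum(vapply(setdiff(genes, g),
               function(other) g %in% members[[other]], logical(1))),
    integer(1))
  nodes <- data.frame(
    gene = genes,
    role = ifelse(genes == seedGene, "seed", "panel"),
    interconnections = as.integer(counts),
    stringsAsFactors = FALSE, row.names = NULL)
  new("InteractionNetwork", nodes = nodes, edges = edges, runs = runs,
      topN = as.integer(topN), membership = membership)
}

#' Grow a gene interaction network by recursive screening
#'
#' Layer 1 screens the whole matrix against the seed probe; the `topK`
#' best-ranked distinct gene symbols (self-hit excluded, multiple probes of
#' one gene collapsed to the gene's best rank) form the panel. Each further
#' layer re-screens the matrix seeded on the best-ranked probe of every new
#' panel gene. Edges and interconnection counts are then assembled with
#' [interactionNetworkFromRuns()]; all rankings are retained for audit.
#'
#' @param m an [ExpressionMatrix-class].
#' @param cfg a [GrowthConfig-class]; `cfg@seedProbe` must be a probe of `m`.
#' @param ann optional probe annotation (see [readProbeAnnotation()]); when
#'   `NULL` every probe is its own gene symbol.
#' @param layer1 optional precomputed [RankedList-class] for the seed probe
#'   (avoids re-screening when the ranking already exists).
#' @return An [InteractionNetwork-class]; stored rankings are available via
#'   [networkRuns()].
#' @export
growNetwork <- function(m, cfg, ann = NULL, layer1 = NULL) {
  if (!cfg@seedProbe %in% probeIds(m))
    stop("seed probe '", cfg@seedProbe, "' not in matrix")
  seedGene <- if (is.null(ann)) cfg@seedProbe
              else unname(mapProbesToSymbols(cfg@seedProbe, ann))
  r1 <- if (is.null(layer1)) screenAll(m, cfg@seedProbe, cfg@screen, ann)
        else layer1
  runs <- stats::setNames(list(r1), seedGene)
  screened <- seedGene
  frontierRuns <- list(r1)
  depth <- 1L
  while (depth < cfg@depth && cfg@topK > 0L) {
    newGenes <- list()
    for (run in frontierRuns) {
      panel <- runGenePanel(run, ann, cfg@topN)
      panel <- panel[!panel$gene %in% screened, , drop = FALSE]
      usable <- !panel$degenerate
      if (any(!usable)) {
        warning("panel gene(s) dropped (no usable probe): ",
                paste(panel$gene[!usable], collapse = ", "))
        panel <- panel[usable, , drop = FALSE]
      }
      panel <- panel[seq_len(min(cfg@topK, nrow(panel))), , drop = FALSE]
      for (i in seq_len(nrow(panel)))
        if (!panel$gene[i] %in% names(newGenes))
          newGenes[[panel$gene[i]]] <- panel$probe_id[i]
    }
    frontierRuns <- list()
    for (g in names(newGenes)) {
      if (g %in% screened) next
      r <- screenAll(m, newGenes[[g]], cfg@screen, ann)
      runs[[g]] <- r
      frontierRuns[[length(frontierRuns) + 1L]] <- r
      screened <- c(screened, g)
    }
    depth <- depth + 1L
  }
  interactionNetworkFromRuns(runs, seedGene = seedGene, ann = ann,
                             topN = cfg@topN, membership = cfg@membership,
                             topK = cfg@topK)
}

#' Tabulate cross-run gene frequencies
#'
#' For every gene symbol appearing in the membership head (first `topN`
#' entries) of any run, counts the number of runs containing at least one of
#' its probes, mirroring the frequency-out-of-n-runs summary of recurring
#' genes across panel screenings.
#'
#' @param runs list of [RankedList-class] objects.
#' @param ann optional probe annotation.
#' @param minFrequency report only genes present in at least this many runs.
#' @param topN membership-head length (default 100).
#' @return data.frame with columns `gene_symbol`, `probes`
#'   (comma-separated contributing probe IDs), `frequency`, `n_runs`,
#'   `probe_multiplicity` (`"Single probe"`/`"Multiple probes"`), sorted by
#'   descending frequency then symbol.
#' @export
frequencyTable <- function(runs, ann = NULL, minFrequency = 1, topN = 100) {
  stopifnot(length(runs) >= 1)
  perRun <- lapply(runs, function(run) {
    head <- run@scores[seq_len(min(topN, nrow(run@scores))), , drop = FALSE]
    sym <- if (is.null(ann)) head$gene_symbol
           else unname(mapProbesToSymbols(head$probe_id, ann))
    data.frame(gene = sym, probe_id = head$probe_id,
               stringsAsFactors = FALSE)
  })
  allGenes <- sort(unique(unlist(lapply(perRun, `[[`, "gene"))))
  rows <- lapply(allGenes, function(g) {
    freq <- sum(vapply(perRun, function(df) g %in% df$gene, logical(1)))
    probes <- sort(unique(unlist(
      lapply(perRun, function(df) df$probe_id[df$gene == g]))))
    data.frame(gene_symbol = g, probes = paste(probes, collapse = ","),
               frequency = freq, n_runs = length(runs),
               probe_multiplicity = if (length(probes) > 1) "Multiple probes"
                                    else "Single probe",
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[tab$frequency >= minFrequency, , drop = FALSE]
  tab <- tab[order(-tab$frequency, tab$gene_symbol, method = "radix"), ,
             drop = FALSE]
  row.names(tab) <- NULL
  tab
}

#' Export an interaction network
#'
#' Formats: `"sif"` (lines `source<TAB>interacts_with<TAB>target`), `"tsv"`
#' (header `source`, `target`, `member_rank`; re-parsing reproduces the edge
#' set exactly), `"graphml"` (node attributes `role` and `interconnections`).
#'
#' @param net an [InteractionNetwork-class].
#' @param path output file path.
#' @param format one of `"sif"`, `"tsv"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
exportNetwork <- function(net, path, format = c("sif", "tsv", "graphml")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown format: ",
                                              format[1]))
  e <- networkEdges(net)
  if (format == "sif") {
    lines <- if (nrow(e)) sprintf("%s\tinteracts_with\t%s", e$from, e$to)
             else character(0)
    writeLines(lines, path)
  } else if (format == "tsv") {
    fwrite(data.frame(source = e$from, target = e$to,
                      member_rank = e$member_rank),
           path, sep = "\t", quote = FALSE)
  } else {
    n <- networkNodes(net)
    g <- igraph::graph_from_data_frame(
      e[, c("from", "to", "member_rank")], directed = TRUE, vertices = n)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
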