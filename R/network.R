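#' Mantel test between two distance matrices
#'
#' Correlates the upper triangles of two distance matrices and assesses
#' significance by jointly permuting rows and columns of the second matrix.
#' One-sided upper-tail p:
#' \deqn{p = (1 + \#\{r_{perm} \ge r_{obs}\}) / (1 + permutations)}.
#'
#' @param D1,D2 symmetric distance matrices with zero diagonal, same size
#'   (>= 4).
#' @param permutations number of permutations (default 1999).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param seed RNG seed.
#' @return list with `r`, `p`, `permutations`, `method`.
#' @export
mantel_test <- function(D1, D2, permutations = 1999,
                        method = c("pearson", "spearman"), seed = 1) {
  method <- match.arg(method)
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  n <- nrow(D1)
  if (n < 4L || !all(dim(D1) == n) || !all(dim(D2) == n))
    stop("distance matrices must be square, equal size >= 4")
  if (max(abs(D1 - t(D1))) > 1e-8 || max(abs(D2 - t(D2))) > 1e-8)
    stop("distance matrices must be symmetric")
  if (any(abs(diag(D1)) > 1e-8) || any(abs(diag(D2)) > 1e-8))
    stop("distance matrices must have zero diagonal")
  ut <- upper.tri(D1)
  v1 <- D1[ut]
  if (method == "spearman") v1 <- rank(v1)
  corfun <- function(m) {
    v2 <- m[ut]
    if (method == "spearman") v2 <- rank(v2)
    stats::cor(v1, v2)
  }
  r_obs <- corfun(D2)
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(permutations)) {
    pm <- sample.int(n)
    if (corfun(D2[pm, pm]) >= r_obs) exceed <- exceed + 1L
  }
  list(r = r_obs, p = (1 + exceed) / (1 + permutations),
       permutations = permutations, method = method)
}

#' Assemble the ASV-QTL-gene-hotspot regulatory network
#'
#' Builds the edge list connecting microbial features to the host loci and
#' genes that regulate them: ASV-QTL edges from significant GWAS hits,
#' ASV-gene edges from significant TWAS hits, and gene-hotspot edges for
#' eGenes whose distant eQTL falls inside a hotspot region.
#'
#' @param gwas_qtl data.frame with columns `asv`, `qtl` (significant
#'   GWAS QTL per ASV); may be empty.
#' @param twas data.frame with columns `asv`, `gene`; may be empty.
#' @param eqtl data.frame with columns `gene`, `chrom`, `pos` (distant-eQTL
#'   lead positions per eGene); may be empty.
#' @param hotspots data.frame from [detect_hotspots()] (columns `chrom`,
#'   `start`, `end`); may be empty.
#' @param environment label attached to every edge.
#' @return list with `edges` (source, source_kind, target, target_kind,
#'   environment, evidence) and `degrees` (node, kind, degree).
#' @export
assemble_network <- function(gwas_qtl = NULL, twas = NULL, eqtl = NULL,
                             hotspots = NULL, environment = "") {
  edges <- list()
  add <- function(src, skind, tgt, tkind, evidence) {
    data.frame(source = src, source_kind = skind, target = tgt,
               target_kind = tkind, environment = environment,
               evidence = evidence, stringsAsFactors = FALSE)
  }
  if (!is.null(gwas_qtl) && nrow(gwas_qtl))
    edges[[length(edges) + 1L]] <- add(gwas_qtl$asv, "ASV", gwas_qtl$qtl, "QTL", "gwas")
  if (!is.null(twas) && nrow(twas))
    edges[[length(edges) + 1L]] <- add(twas$asv, "ASV", twas$gene, "gene", "twas")
  if (!is.null(eqtl) && nrow(eqtl) && !is.null(hotspots) && nrow(hotspots)) {
    for (i in seq_len(nrow(hotspots))) {
      inside <- eqtl$chrom == hotspots$chrom[i] &
        eqtl$pos >= hotspots$start[i] & eqtl$pos <= hotspots$end[i]
      if (any(inside)) {
        hid <- sprintf("hotspot_%s:%d-%d", hotspots$chrom[i],
                       as.integer(hotspots$start[i]), as.integer(hotspots$end[i]))
        edges[[length(edges) + 1L]] <-
          add(unique(eqtl$gene[inside]), "gene", hid, "hotspot", "eqtl")
      }
    }
  }
  if (!length(edges)) {
    el <- data.frame(source = character(0), source_kind = character(0),
                     target = character(0), target_kind = character(0),
                     environment = character(0), evidence = character(0),
                     stringsAsFactors = FALSE)
    return(list(edges = el,
                degrees = data.frame(node = character(0), kind = character(0),
                                     degree = integer(0))))
  }
  el <- unique(do.call(rbind, edges))
  if (any(el$source == el$target)) stop("integrity error: self-edge in network")
  rownames(el) <- NULL
  nodes <- rbind(data.frame(node = el$source, kind = el$source_kind),
                 data.frame(node = el$target, kind = el$target_kind))
  deg <- stats::aggregate(list(degree = rep(1L, nrow(nodes))),
                          by = list(node = nodes$node, kind = nodes$kind), FUN = sum)
  deg <- deg[order(-deg$degree, deg$node), ]
  rownames(deg) <- NULL
  list(edges = el, degrees = deg)
}
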