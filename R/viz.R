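# Static renderings of the three views: association graph, genotype view,
# heatmap. All renderings are deterministic functions of their inputs plus
# the layout seed; SVG output is byte-stable.

BASE_COLORS <- c(A = "#4CAF50", C = "#2196F3", G = "#FFC107", T = "#F44336")
STATE_FILL <- c(REF = "#FFFFFF", HET = "#808080", HOM = "#000000")
GROUP_COLORS <- c(affected = "#FF8C00", unaffected = "#00CED1")

#' Render the association gene network
#'
#' Genes are circles (palette fill for colored nodes, gray otherwise), every
#' edge is drawn in the color of its color gene with stroke width growing
#' with log weight and the weight printed at the midpoint. Multi-edges
#' between the same endpoints are drawn as separate offset curves;
#' self-loops as small circles beside the node. Layout is a seeded
#' force-directed (Fruchterman-Reingold) embedding, so a fixed
#' `layoutSeed` gives identical output bytes.
#'
#' @param graph an [AssocGraph-class]; must contain at least one node.
#' @param path output file.
#' @param width,height canvas size in pixels.
#' @param palette colors for [assignNodeColors()] (skipped if the graph
#'   already has concrete colors).
#' @param layoutSeed integer seed for the layout.
#' @param format `"svg"` or `"png"`; default inferred from `path`.
#' @return the path, invisibly.
#' @export
renderAssociationGraph <- function(graph, path, width = 800L, height = 600L,
                                   palette = defaultNodePalette(),
                                   layoutSeed = 1L, format = NULL) {
  if (length(graph@nodes) == 0L) stop("cannot render an empty graph")
  if (all(is.na(graph@colors))) graph <- assignNodeColors(graph, palette)
  nodes <- graph@nodes
  set.seed(layoutSeed)
  e <- edgeTable(graph)
  ig <- igraph::graph_from_data_frame(
    if (nrow(e)) unique(data.frame(from = e$gene_a, to = e$gene_b)[
      e$gene_a != e$gene_b, , drop = FALSE])
    else data.frame(from = character(), to = character()),
    directed = FALSE, vertices = data.frame(name = nodes))
  xy <- igraph::layout_with_fr(ig)
  margin <- 60
  rescale <- function(v, lo, hi) {
    if (diff(range(v)) < 1e-9) return(rep((lo + hi) / 2, length(v)))
    lo + (v - min(v)) / diff(range(v)) * (hi - lo)
  }
  X <- stats::setNames(rescale(xy[, 1L], margin, width - margin), nodes)
  Y <- stats::setNames(rescale(xy[, 2L], margin, height - margin), nodes)
  cv <- newCanvas(width, height)
  if (nrow(e)) {
    grpKey <- paste(e$gene_a, e$gene_b)
    grpIdx <- stats::ave(seq_len(nrow(e)), grpKey, FUN = seq_along)
    grpN <- stats::ave(seq_len(nrow(e)), grpKey, FUN = length)
    for (i in seq_len(nrow(e))) {
      col <- unname(graph@colors[e$color_gene[i]])
      w <- 1 + 1.5 * log10(e$weight[i] + 1)
      x1 <- X[e$gene_a[i]]; y1 <- Y[e$gene_a[i]]
      x2 <- X[e$gene_b[i]]; y2 <- Y[e$gene_b[i]]
      if (e$gene_a[i] == e$gene_b[i]) {
        cvCircle(cv, x1 + 18 + 6 * grpIdx[i], y1 - 18 - 6 * grpIdx[i],
                 10 + 3 * grpIdx[i], fill = "none", stroke = col)
        cvText(cv, x1 + 18 + 6 * grpIdx[i], y1 - 32 - 6 * grpIdx[i],
               as.character(e$weight[i]), size = 9, fill = col)
      } else {
        off <- (grpIdx[i] - (grpN[i] + 1) / 2) * 24
        mx <- (x1 + x2) / 2; my <- (y1 + y2) / 2
        len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
        nx <- -(y2 - y1) / len; ny <- (x2 - x1) / len
        cvCurve(cv, x1, y1, mx + nx * off * 2, my + ny * off * 2, x2, y2,
                stroke = col, width = w)
        cvText(cv, mx + nx * off, my + ny * off - 3,
               as.character(e$weight[i]), size = 9, fill = col)
      }
    }
  }
  for (g in nodes) {
    fill <- unname(graph@colors[g])
    cvCircle(cv, X[g], Y[g], 14, fill = fill, stroke = "#333333")
    cvText(cv, X[g], Y[g] - 18, g, size = 11)
  }
  invisible(renderCanvas(cv, path, formatFromPath(path, format)))
}

genotypeGlyph <- function(cv, x, y, w, h, call) {
  if (is.na(call)) {
    cvRect(cv, x, y, w, h, fill = "#DDDDDD", stroke = "#999999")
    return(invisible(cv))
  }
  a1 <- substr(call, 1L, 1L); a2 <- substr(call, 2L, 2L)
  if (a1 == a2) {            # homozygous: solid color
    cvRect(cv, x, y, w, h, fill = BASE_COLORS[[a1]], stroke = "#333333")
  } else {                   # heterozygous: split fill stands in for hashing
    cvRect(cv, x, y, w / 2, h, fill = BASE_COLORS[[a1]], stroke = "none")
    cvRect(cv, x + w / 2, y, w / 2, h, fill = BASE_COLORS[[a2]],
           stroke = "none")
    cvRect(cv, x, y, w, h, fill = "none", stroke = "#333333")
  }
  invisible(cv)
}

#' Render the genotype view
#'
#' One column per SNP, six sectors top to bottom: the -log10 p significance
#' bar; the SNP identifier; the cohort genotype distribution (affected and
#' unaffected sub-columns, bands for identical genotypes horizontally
#' aligned, alphabetical order); the cohort genotype summary (box height =
#' consensus strength, fill white/gray/black for REF/HET/HOM, side-by-side
#' or stacked); the reference base; and the focus patient's call.
#' Homozygous calls are solid base colors, heterozygous calls split
#' two-color fills.
#'
#' @param view data.frame from [buildGenotypeViewModel()].
#' @param path output file.
#' @param mode `"side_by_side"` or `"stacked"` consensus boxes.
#' @param colWidth column width in pixels.
#' @param format `"svg"` or `"png"`; default inferred from `path`.
#' @return the path, invisibly.
#' @export
renderGenotypeView <- function(view, path, mode = c("side_by_side",
                                                    "stacked"),
                               colWidth = 28L, format = NULL) {
  mode <- match.arg(mode)
  stopifnot(nrow(view) >= 1L)
  secH <- c(bar = 60, id = 14, dist = 120, summary = 48, ref = 16,
            indiv = 16)
  pad <- 4
  width <- 40L + as.integer(nrow(view) * colWidth)
  height <- as.integer(sum(secH) + 7 * pad)
  cv <- newCanvas(width, height)
  maxBar <- max(c(view$neg_log_p, 1), na.rm = TRUE)
  for (i in seq_len(nrow(view))) {
    x0 <- 40 + (i - 1) * colWidth + 2
    wc <- colWidth - 4
    y <- pad
    # 1: significance bar
    v <- view$neg_log_p[i]
    if (!is.na(v)) {
      bh <- v / maxBar * secH[["bar"]]
      cvRect(cv, x0 + wc / 4, y + secH[["bar"]] - bh, wc / 2, bh,
             fill = if (isTRUE(view$relevant[i])) "#D32F2F" else "#555555")
    }
    y <- y + secH[["bar"]] + pad
    # 2: identifier
    cvText(cv, x0 + wc / 2, y + 10, view$snp_id[i], size = 6)
    y <- y + secH[["id"]] + pad
    # 3: cohort distribution, aligned bands per genotype
    da <- view$dist_affected[[i]]; du <- view$dist_unaffected[[i]]
    cats <- sort(unique(c(names(da), names(du))))
    if (length(cats)) {
      pa <- ifelse(is.na(da[cats]), 0, da[cats]) / max(sum(da), 1L)
      pu <- ifelse(is.na(du[cats]), 0, du[cats]) / max(sum(du), 1L)
      bandH <- pmax(pa, pu)
      scale <- secH[["dist"]] / max(sum(bandH), 1e-9)
      yy <- y
      for (k in seq_along(cats)) {
        for (side in 1:2) {
          p <- if (side == 1) pa[k] else pu[k]
          if (p > 0) {
            genotypeGlyph(cv, x0 + (side - 1) * wc / 2, yy, wc / 2 - 1,
                          p * scale, cats[k])
          }
        }
        yy <- yy + bandH[k] * scale
      }
    }
    y <- y + secH[["dist"]] + pad
    # 4: cohort summary boxes
    states <- c(view$consensus_affected[i], view$consensus_unaffected[i])
    strengths <- c(view$strength_affected[i], view$strength_unaffected[i])
    if (mode == "side_by_side") {
      for (side in 1:2) {
        if (!is.na(states[side])) {
          bh <- strengths[side] * secH[["summary"]]
          cvRect(cv, x0 + (side - 1) * wc / 2, y + secH[["summary"]] - bh,
                 wc / 2 - 1, bh, fill = STATE_FILL[[states[side]]],
                 stroke = "#333333")
        }
      }
    } else {
      half <- secH[["summary"]] / 2
      for (side in 1:2) {
        if (!is.na(states[side])) {
          bh <- strengths[side] * half
          cvRect(cv, x0, y + side * half - bh, wc, bh,
                 fill = STATE_FILL[[states[side]]], stroke = "#333333")
        }
      }
    }
    y <- y + secH[["summary"]] + pad
    # 5: reference base
    ref <- view$ref_allele[i]
    cvRect(cv, x0, y, wc, secH[["ref"]] - 2, fill = BASE_COLORS[[ref]],
           stroke = "#333333")
    cvText(cv, x0 + wc / 2, y + secH[["ref"]] - 6, ref, size = 8,
           fill = "#FFFFFF")
    y <- y + secH[["ref"]] + pad
    # 6: individual patient call
    genotypeGlyph(cv, x0, y, wc, secH[["indiv"]] - 2,
                  view$individual_call[i])
  }
  invisible(renderCanvas(cv, path, formatFromPath(path, format)))
}

rampGreenRed <- function(v, m) {
  if (m <= 0) return(rep("#000000", length(v)))
  t <- pmax(-1, pmin(1, v / m))
  up <- pmin(pmax(t, 0), 1)      # red side
  dn <- pmin(pmax(-t, 0), 1)     # green side
  grDevices::rgb(up, dn, 0)
}

#' Render the expression heatmap
#'
#' Per-gene centered expression mapped to a symmetric green-red gradient
#' (green low, red high, black at zero). Patients are grouped by disease
#' state under a colored group bar (orange affected, cyan unaffected); genes
#' are rows sorted by FDR-corrected p (most significant on top) with a
#' blue-white significance swatch, centered on q = 0.05, at the left. With
#' `aggregate = TRUE` the two group mean profiles are drawn instead of
#' individual patients.
#'
#' @param expr numeric matrix, genes x patients.
#' @param stats data.frame from [geneStats()] covering all genes.
#' @param patients phenotype data.frame.
#' @param path output file.
#' @param aggregate render group mean profiles instead of patients.
#' @param cellHeight row height in pixels.
#' @param format `"svg"` or `"png"`; default inferred from `path`.
#' @return the path, invisibly.
#' @export
renderHeatmap <- function(expr, stats, patients, path, aggregate = FALSE,
                          cellHeight = 14L, format = NULL) {
  stopifnot(all(rownames(expr) %in% stats$gene))
  ord <- stats$gene[order(stats$q, stats$p, stats$gene)]
  ord <- ord[ord %in% rownames(expr)]
  mat <- expr[ord, , drop = FALSE]
  if (aggregate) {
    mat <- groupMeanProfiles(mat, patients)
    groups <- factor(colnames(mat), levels = c("affected", "unaffected"))
  } else {
    pid <- patients$patient_id[order(patients$group)]
    pid <- pid[pid %in% colnames(mat)]
    mat <- mat[, pid, drop = FALSE]
    groups <- patients$group[match(pid, patients$patient_id)]
  }
  centered <- mat - rowMeans(mat)
  m <- max(abs(centered))
  left <- 120; top <- 26
  cw <- max(2, min(18, round(760 / ncol(mat))))
  width <- as.integer(left + cw * ncol(mat) + 20)
  height <- as.integer(top + cellHeight * nrow(mat) + 16)
  cv <- newCanvas(width, height)
  # group color bar
  for (j in seq_len(ncol(mat))) {
    cvRect(cv, left + (j - 1) * cw, top - 12, cw, 8,
           fill = GROUP_COLORS[[as.character(groups[j])]])
  }
  qv <- stats$q[match(rownames(mat), stats$gene)]
  for (i in seq_len(nrow(mat))) {
    yy <- top + (i - 1) * cellHeight
    # significance swatch: blue below q = 0.05 fading to white above
    t <- pmax(0, pmin(1, 0.5 + (0.05 - qv[i]) * 10))
    cvRect(cv, 2, yy, 12, cellHeight - 1,
           fill = grDevices::rgb(1 - t, 1 - t, 1), stroke = "#888888")
    cvText(cv, 18, yy + cellHeight - 4, rownames(mat)[i], size = 9,
           anchor = "start")
    cols <- rampGreenRed(centered[i, ], m)
    for (j in seq_len(ncol(mat))) {
      cvRect(cv, left + (j - 1) * cw, yy, cw, cellHeight - 1,
             fill = cols[j])
    }
  }
  invisible(renderCanvas(cv, path, formatFromPath(path, format)))
}
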