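#' Built-in library of chromatin profile shape templates
#'
#' Five canonical 60-bin shape families observed around TSSs: a symmetric
#' peak with a central dip (nucleosome-depleted region flanked by positioned
#' nucleosomes), a central peak without a dip (retained +1/-1 nucleosome, the
#' poised configuration), a downstream ramp (signal rising in the transcript
#' direction), its upstream mirror, and a flat enrichment. All templates are
#' non-negative and sum to 1.
#'
#' @return named list of `shape_template` objects (`name`, `values`).
#' @export
builtin_shape_library <- function() {
  x <- seq_len(60L)
  gauss <- function(mu, sigma) exp(-(x - mu)^2 / (2 * sigma^2))
  dip <- gauss(25, 3) + gauss(36, 3)           # bumps at ~-550 / +550 bp
  nodip <- gauss(30.5, 3)                      # single central peak
  down <- pmax(0, pmin(1, (x - 26) / 10))      # ramps up in transcript direction
  up <- rev(down)
  flat <- rep(1, 60L)
  templates <- list(dip = dip, nodip = nodip, downstream_ramp = down,
                    upstream_ramp = up, flat = flat)
  lapply(names(templates), function(nm) {
    v <- templates[[nm]]
    structure(list(name = nm, values = v / sum(v)), class = "shape_template")
  }) -> out
  names(out) <- names(templates)
  out
}

#' Per-metacluster shape-template archetypes
#'
#' An n_meta x n_marks matrix of template indices into
#' [builtin_shape_library()] defining the combinatorial chromatin
#' configuration planted for each metacluster. Expressed RTSSs keep a
#' nucleosome-depleted centre, so archetypes draw on the dip and the two ramp
#' shapes (the central-peak shape is reserved for the poised configuration).
#' The first nine archetypes are the words of a ternary linear code over the
#' marks, giving a pairwise Hamming distance of at least 4 (for six marks);
#' further archetypes are added by deterministic greedy search maximising the
#' minimum Hamming distance to the existing rows.
#'
#' @param marks character vector of active-mark names (>= 2).
#' @param n_meta number of metaclusters (default 10).
#' @return integer matrix (n_meta x length(marks)), dimnames set.
#' @export
metacluster_archetypes <- function(marks, n_meta = 10L) {
  nm <- length(marks)
  stopifnot(nm >= 2L)
  alphabet <- c(1L, 3L, 4L)   # dip, downstream ramp, upstream ramp
  words <- matrix(0L, nrow = 0L, ncol = nm)
  for (a in 0:2) {
    for (b in 0:2) {
      if (nrow(words) >= n_meta) break
      words <- rbind(words, (a + b * seq_len(nm)) %% 3L)
    }
  }
  while (nrow(words) < n_meta) {
    # all candidate ternary words, first lexicographic maximiser of the
    # minimum Hamming distance to the chosen rows
    cand <- as.matrix(expand.grid(rep(list(0:2), nm)))[, nm:1, drop = FALSE]
    dmin <- apply(cand, 1L, function(w) {
      min(rowSums(sweep(words, 2L, w, "!=")))
    })
    words <- rbind(words, cand[which.max(dmin), ])
  }
  arch <- matrix(alphabet[words[seq_len(n_meta), , drop = FALSE] + 1L],
                 nrow = n_meta, ncol = nm,
                 dimnames = list(paste0("mc", seq_len(n_meta)), marks))
  arch
}

#' Generate a synthetic genome with non-overlapping genes
#'
#' Chromosomes of equal length; genes placed uniformly with a 10 kbp
#' inter-gene margin and 5 kbp clearance from chromosome ends, random strand,
#' lengths uniform in 14-30 kbp.
#'
#' @param n_chroms number of chromosomes (default 2).
#' @param chrom_length chromosome length in bp (default 25e6).
#' @param n_genes number of genes (default 300).
#' @param seed integer seed.
#' @return list with `chrom_sizes` (named vector) and `genes`
#'   (gene annotation data.frame with `tss`).
#' @export
generate_genome <- function(n_chroms = 2L, chrom_length = 25e6, n_genes = 300L,
                            seed = 1L) {
  set.seed(seed)
  chrom_sizes <- setNames(rep(as.integer(chrom_length), n_chroms),
                          paste0("chr", seq_len(n_chroms)))
  if (n_genes == 0L) {
    return(list(chrom_sizes = chrom_sizes,
                genes = gene_annotation(data.frame(
                  gene_id = character(), chrom = character(),
                  strand = character(), txStart = integer(),
                  txEnd = integer()))))
  }
  # inter-gene margin exceeds the 6 kbp profile reach so that different gene
  # neighbourhoods cannot contaminate each other's chromatin windows
  margin <- 10000L; edge <- 5000L
  per_chrom <- table(factor(sample(names(chrom_sizes), n_genes, replace = TRUE),
                            levels = names(chrom_sizes)))
  rows <- list()
  for (chrom in names(chrom_sizes)) {
    ng <- per_chrom[[chrom]]
    if (ng == 0L) next
    placed_start <- integer(0); placed_end <- integer(0)
    for (g in seq_len(ng)) {
      len <- as.integer(round(runif(1, 14000, 30000)))
      ok <- FALSE
      for (attempt in seq_len(2000L)) {
        s <- as.integer(floor(runif(1, edge, chrom_length - edge - len)))
        if (!length(placed_start) ||
            all(s + len + margin <= placed_start | s >= placed_end + margin)) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("gene density infeasible: could not place gene on ", chrom)
      placed_start <- c(placed_start, s); placed_end <- c(placed_end, s + len)
    }
    rows[[chrom]] <- data.frame(chrom = chrom, txStart = placed_start,
                                txEnd = placed_end)
  }
  genes <- do.call(rbind, rows)
  genes <- genes[order(genes$chrom, genes$txStart), , drop = FALSE]
  genes$gene_id <- sprintf("g%04d", seq_len(nrow(genes)))
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
  rownames(genes) <- NULL
  list(chrom_sizes = chrom_sizes,
       genes = gene_annotation(genes[, c("gene_id", "chrom", "strand",
                                         "txStart", "txEnd")]))
}

#' Default planted class-fraction matrix
#'
#' Expression class by location class fractions, echoing the observed pattern
#' that intra-/intergenic RTSSs are dominated by repressed RTSSs while
#' annotated/proximal RTSSs are dominated by expressed ones.
#'
#' @return 3 x 4 matrix summing to 1 (rows expressed/repressed/intermediate,
#'   columns annotated/proximal/intragenic/intergenic).
#' @export
default_class_fractions <- function() {
  m <- rbind(
    expressed = c(0.06, 0.08, 0.12, 0.06),
    repressed = c(0.03, 0.05, 0.28, 0.20),
    intermediate = c(0.02, 0.02, 0.05, 0.03)
  )
  colnames(m) <- c("annotated", "proximal", "intragenic", "intergenic")
  m
}

# Place one RTSS of a given location class. Chromatin-enriched RTSSs
# (expressed or poised) either co-locate in a gene's TSS cluster (offsets
# <= ~150 bp, which preserves profile shape) or keep >= `space` bp from every
# other enriched anchor, so each enriched profile window holds one coherent
# chromatin domain. `occupied` is an environment holding, per chromosome, the
# anchors of free-standing enriched RTSSs already placed.
place_rtss <- function(loc, enriched, genes, chrom_sizes, occupied,
                       space = 6500L) {
  clear_of <- function(chrom, anchor) {
    !enriched || all(abs(occupied[[chrom]] - anchor) >= space)
  }
  register <- function(chrom, anchor) {
    if (enriched) occupied[[chrom]] <- c(occupied[[chrom]], anchor)
  }
  if (loc == "intergenic") {
    gene_margin <- if (enriched) space else 650L
    for (attempt in seq_len(5000L)) {
      chrom <- sample(names(chrom_sizes), 1L)
      w <- sample(20:80, 1L)
      anchor <- as.integer(floor(runif(1, 5000, chrom_sizes[[chrom]] - 5000)))
      g <- genes[genes$chrom == chrom, , drop = FALSE]
      if ((!nrow(g) || all(anchor + w < g$txStart - gene_margin |
                             anchor - w > g$txEnd + gene_margin)) &&
            clear_of(chrom, anchor)) {
        register(chrom, anchor)
        start <- anchor - w %/% 2L
        return(list(chrom = chrom, start = start, end = start + w,
                    strand = sample(c("+", "-"), 1L), gene = NA_character_))
      }
    }
    stop("could not place an intergenic RTSS at the requested density")
  }
  if (loc == "intragenic") {
    # clear of both gene ends and, for enriched RTSSs, of the TSS cluster
    # and of other enriched anchors
    for (attempt in seq_len(5000L)) {
      g <- genes[sample.int(nrow(genes), 1L), ]
      w <- sample(20:80, 1L)
      anchor <- as.integer(floor(runif(1, g$txStart + 400, g$txEnd - 400)))
      if (enriched && abs(anchor - g$tss) < space) next
      if (!clear_of(g$chrom, anchor)) next
      register(g$chrom, anchor)
      start <- anchor - w %/% 2L
      return(list(chrom = g$chrom, start = start, end = start + w,
                  strand = sample(c("+", "-"), 1L), gene = g$gene_id))
    }
    stop("could not place an intragenic RTSS at the requested density")
  }
  g <- genes[sample.int(nrow(genes), 1L), ]
  if (loc == "annotated") {
    w <- sample(20:80, 1L)
    start <- g$tss - sample.int(w, 1L) + 1L   # interval contains the TSS base
    return(list(chrom = g$chrom, start = start, end = start + w,
                strand = g$strand, gene = g$gene_id))
  }
  # proximal: anchor within +/-150 bp of the TSS, interval excluding it
  w <- sample(20:60, 1L)
  d <- sample(40:148, 1L) * sample(c(-1L, 1L), 1L)
  start <- g$tss + d - w %/% 2L
  list(chrom = g$chrom, start = start, end = start + w,
       strand = g$strand, gene = g$gene_id)
}

#' Generate a synthetic RTSS catalog with expression and planted truth
#'
#' RTSSs are placed per the class-fraction matrix relative to the gene
#' annotation; CAGE tag counts follow a negative-binomial model with latent
#' log-activity factors shared within gene neighbourhoods (inducing positive
#' expression correlation among RTSSs near a common gene) and within planted
#' metaclusters (inducing the co-expression that window-correlation
#' validation measures). In the focal sample (the first), expressed RTSSs
#' have counts of at least `threshold`, repressed RTSSs have exactly 0, and
#' intermediate RTSSs fall strictly between. A fraction of repressed RTSSs is
#' flagged poised; metacluster labels are planted on expressed RTSSs only.
#'
#' @param genome output of [generate_genome()].
#' @param n_rtss number of RTSSs (default 2000).
#' @param class_fractions 3 x 4 fraction matrix (see
#'   [default_class_fractions()]); must sum to 1.
#' @param S number of samples (>= 2, default 100; sample 1 is focal).
#' @param threshold expressed-class tag threshold (default 5).
#' @param n_meta number of planted metaclusters (default 10).
#' @param poised_fraction fraction of repressed RTSSs flagged poised
#'   (default 0.1).
#' @param neighborhood_sd sd of the shared gene-neighbourhood log-activity
#'   (default 0.5; 0 disables neighbourhood correlation).
#' @param cluster_sd sd of the shared metacluster log-activity (default 0.7).
#' @param nb_size negative-binomial size (dispersion) parameter (default 5).
#' @param seed integer seed.
#' @return list with `catalog`, `expr` (matrix), `truth` (data.frame with
#'   rtss_id, expression_class, location_class, metacluster, poised, gene_id).
#' @export
generate_rtss_set <- function(genome, n_rtss = 2000L,
                              class_fractions = default_class_fractions(),
                              S = 100L, threshold = 5L, n_meta = 10L,
                              poised_fraction = 0.1, neighborhood_sd = 0.5,
                              cluster_sd = 0.7, nb_size = 5, seed = 1L) {
  if (S < 2L) stop("S must be >= 2 (correlation validation undefined)")
  if (abs(sum(class_fractions) - 1) > 1e-8) stop("class fractions must sum to 1")
  set.seed(seed)
  genes <- genome$genes
  combos <- expand.grid(expr = rownames(class_fractions),
                        loc = colnames(class_fractions),
                        stringsAsFactors = FALSE)
  probs <- mapply(function(e, l) class_fractions[e, l], combos$expr, combos$loc)
  assign <- sample.int(nrow(combos), n_rtss, replace = TRUE, prob = probs)
  expr_class <- combos$expr[assign]
  loc_class <- combos$loc[assign]
  needs_gene <- loc_class != "intergenic"
  if (any(needs_gene) && nrow(genes) == 0L) {
    stop("gene-anchored location classes require a non-empty gene annotation")
  }

  # poised flags are drawn before placement (placement spacing depends on
  # which RTSSs carry chromatin); poised RTSSs live in intra-/intergenic
  # space, away from active TSS clusters whose reads would otherwise mask
  # their central-peak signature
  poised <- rep(FALSE, n_rtss)
  rep_idx <- which(expr_class == "repressed" &
                     loc_class %in% c("intragenic", "intergenic"))
  n_poised <- round(poised_fraction * sum(expr_class == "repressed"))
  n_poised <- min(n_poised, length(rep_idx))
  poised[sample(rep_idx, n_poised)] <- TRUE

  enriched <- expr_class == "expressed" | poised
  occupied <- new.env(parent = emptyenv())
  for (chrom in names(genome$chrom_sizes)) occupied[[chrom]] <- numeric(0)
  placed <- lapply(seq_len(n_rtss), function(i) {
    place_rtss(loc_class[i], enriched[i], genes, genome$chrom_sizes, occupied)
  })
  catalog <- rtss_catalog(data.frame(
    id = sprintf("r%05d", seq_len(n_rtss)),
    chrom = vapply(placed, `[[`, "", "chrom"),
    start = vapply(placed, function(p) as.integer(p$start), integer(1)),
    end = vapply(placed, function(p) as.integer(p$end), integer(1)),
    strand = vapply(placed, `[[`, "", "strand"),
    stringsAsFactors = FALSE
  ))
  gene_id <- vapply(placed, `[[`, "", "gene")
  # intergenic RTSSs still join the neighbourhood of a gene within 50 kbp
  for (i in which(is.na(gene_id))) {
    g <- genes[genes$chrom == catalog$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    d <- abs(g$tss - catalog$anchor[i])
    if (min(d) <= 50000L) gene_id[i] <- g$gene_id[which.min(d)]
  }

  # metacluster labels are planted per gene neighbourhood: co-located RTSSs
  # share chromatin context, so expressed RTSSs anchored at the same gene get
  # the same combinatorial label (gene-less RTSSs draw their own)
  meta <- rep(NA_integer_, n_rtss)
  is_expr <- expr_class == "expressed"
  gene_label <- setNames(
    sample.int(n_meta, nrow(genes), replace = TRUE), genes$gene_id)
  with_gene <- is_expr & !is.na(gene_id)
  meta[with_gene] <- gene_label[gene_id[with_gene]]
  meta[is_expr & is.na(gene_id)] <-
    sample.int(n_meta, sum(is_expr & is.na(gene_id)), replace = TRUE)
  # latent log-activity factors: per (gene, sample) and per (metacluster, sample)
  gene_levels <- unique(gene_id[!is.na(gene_id)])
  a <- matrix(rnorm(length(gene_levels) * S, sd = neighborhood_sd),
              nrow = length(gene_levels), dimnames = list(gene_levels, NULL))
  b <- matrix(rnorm(n_meta * S, sd = cluster_sd), nrow = n_meta)

  counts <- matrix(0L, nrow = n_rtss, ncol = S,
                   dimnames = list(catalog$id, paste0("s", seq_len(S))))
  log_act <- matrix(0, nrow = n_rtss, ncol = S)
  has_gene <- !is.na(gene_id)
  log_act[has_gene, ] <- a[gene_id[has_gene], , drop = FALSE]
  log_act[is_expr, ] <- log_act[is_expr, , drop = FALSE] +
    b[meta[is_expr], , drop = FALSE]
  base_mean <- ifelse(expr_class == "expressed", 30,
                      ifelse(expr_class == "repressed", 3, 5))
  mu <- base_mean * exp(log_act)
  counts[] <- rnbinom(n_rtss * S, mu = mu, size = nb_size)
  # focal-sample contract: expressed >= threshold, repressed == 0,
  # intermediate strictly in between
  counts[is_expr, 1L] <- threshold +
    rnbinom(sum(is_expr), mu = mu[is_expr, 1L], size = nb_size)
  counts[expr_class == "repressed", 1L] <- 0L
  n_int <- sum(expr_class == "intermediate")
  counts[expr_class == "intermediate", 1L] <-
    if (threshold > 1L) sample.int(threshold - 1L, n_int, replace = TRUE)
    else 0L

  truth <- data.frame(rtss_id = catalog$id, expression_class = expr_class,
                      location_class = loc_class, metacluster = meta,
                      poised = poised, gene_id = gene_id,
                      stringsAsFactors = FALSE)
  list(catalog = catalog, expr = counts, truth = truth)
}

#' Generate synthetic ChIP-seq read starts and peaks for a mark panel
#'
#' For every enriched RTSS, `depth` reads are drawn multinomially over the 60
#' oriented bins of its planted shape template, jittered uniformly within
#' bins, assigned a mapped strand 50/50, and then *un*-shifted by -100/+100 bp
#' so that the profiling shift step re-centres them. Uniform background reads
#' are added per chromosome at `noise_rate` reads per kbp. Enrichment peaks of
#' +/-1 kbp around enriched anchors are emitted per mark (unmerged).
#'
#' Enrichment pattern: expressed RTSSs carry every active mark with the shape
#' given by their metacluster archetype; poised RTSSs carry every active mark
#' and Pol II with the no-dip central-peak template; Pol II at expressed
#' RTSSs also uses the central-peak template.
#'
#' @param truth planted-truth data.frame from [generate_rtss_set()].
#' @param catalog matching `rtss_catalog`.
#' @param chrom_sizes named chromosome lengths.
#' @param active_marks character vector of active-mark names.
#' @param archetypes archetype matrix from [metacluster_archetypes()].
#' @param depth reads per enriched RTSS per active mark (default 500).
#' @param poised_depth reads per poised RTSS per active mark (default 300).
#' @param polII_depth,polII_depth_poised Pol II depths at expressed / poised
#'   RTSSs (defaults 600 / 250).
#' @param noise_rate background reads per kbp per mark (default 5).
#' @param shift the shift the profiling step will apply (default 100).
#' @param seed integer seed.
#' @return list with `reads` (named list of `read_starts`) and `peaks`
#'   (named list of peak data.frames), covering `active_marks` and `"PolII"`.
#' @export
generate_chip_reads <- function(truth, catalog, chrom_sizes, active_marks,
                                archetypes = metacluster_archetypes(active_marks),
                                depth = 500L, poised_depth = 300L,
                                polII_depth = 600L, polII_depth_poised = 250L,
                                noise_rate = 5, shift = 100L, seed = 1L) {
  if (depth < 0L) stop("depth must be >= 0")
  set.seed(seed)
  shapes <- builtin_shape_library()
  flank <- 3000L; bin_bp <- 100L
  is_expr <- truth$expression_class == "expressed"
  is_poised <- truth$poised

  draw_group <- function(idx, template_values, n_reads) {
    # multinomial bin counts for all RTSSs in the group, then positions
    if (!length(idx) || n_reads == 0L) {
      return(data.frame(chrom = character(), pos = integer(),
                        strand = character()))
    }
    C <- stats::rmultinom(length(idx), n_reads, template_values)
    bins <- rep(rep(seq_len(60L), length(idx)), as.vector(C))
    ridx <- rep(rep(idx, each = 60L), as.vector(C))
    plus_rtss <- catalog$strand[ridx] == "+"
    gstart <- ifelse(plus_rtss,
                     catalog$anchor[ridx] - flank + (bins - 1L) * bin_bp,
                     catalog$anchor[ridx] + flank - bins * bin_bp)
    pos <- gstart + as.integer(floor(runif(length(gstart)) * bin_bp))
    read_strand <- sample(c("+", "-"), length(pos), replace = TRUE)
    pos <- ifelse(read_strand == "+", pos - shift, pos + shift)  # pre-shift
    data.frame(chrom = catalog$chrom[ridx], pos = pmax(pos, 0L),
               strand = read_strand, stringsAsFactors = FALSE)
  }

  background <- function() {
    parts <- lapply(names(chrom_sizes), function(chrom) {
      n <- stats::rpois(1L, noise_rate * chrom_sizes[[chrom]] / 1000)
      data.frame(chrom = rep(chrom, n),
                 pos = as.integer(floor(runif(n) * chrom_sizes[[chrom]])),
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, parts)
  }

  peaks_for <- function(idx) {
    if (!length(idx)) {
      return(data.frame(chrom = character(), start = integer(),
                        end = integer()))
    }
    df <- data.frame(chrom = catalog$chrom[idx],
                     start = pmax(catalog$anchor[idx] - 1000L, 0L),
                     end = catalog$anchor[idx] + 1000L)
    df[order(df$chrom, df$start), , drop = FALSE]
  }

  reads <- list(); peaks <- list()
  for (m in seq_along(active_marks)) {
    mark <- active_marks[m]
    parts <- list()
    for (tmpl in seq_along(shapes)) {
      idx <- which(is_expr & archetypes[truth$metacluster, m] == tmpl)
      parts[[length(parts) + 1L]] <-
        draw_group(idx, shapes[[tmpl]]$values, depth)
    }
    parts[[length(parts) + 1L]] <-
      draw_group(which(is_poised), shapes$nodip$values, poised_depth)
    parts[[length(parts) + 1L]] <- background()
    df <- do.call(rbind, parts)
    reads[[mark]] <- read_starts(df$chrom, df$pos, df$strand, mark = mark)
    peaks[[mark]] <- peaks_for(which(is_expr | is_poised))
  }
  polII <- rbind(
    draw_group(which(is_expr), shapes$nodip$values, polII_depth),
    draw_group(which(is_poised), shapes$nodip$values, polII_depth_poised),
    background()
  )
  reads[["PolII"]] <- read_starts(polII$chrom, polII$pos, polII$strand,
                                  mark = "PolII")
  peaks[["PolII"]] <- peaks_for(which(is_expr | is_poised))
  list(reads = reads, peaks = peaks)
}

#' Generate a synthetic nucleosome-occupancy signal track
#'
#' Accumulates, on a 100 bp genome grid, a dip-shaped occupancy footprint
#' around expressed RTSSs (nucleosome-depleted region) and a central-peak
#' footprint around poised RTSSs (retained central nucleosome), emitted as a
#' non-overlapping `signal_track`.
#'
#' @param truth,catalog planted truth and catalog.
#' @param scale peak height in arbitrary units (default 10).
#' @param seed integer seed (reserved; generation is deterministic).
#' @return a `signal_track`.
#' @export
generate_nucleosome_track <- function(truth, catalog, scale = 10, seed = 1L) {
  shapes <- builtin_shape_library()
  flank <- 3000L; bin_bp <- 100L
  sel <- which(truth$expression_class == "expressed" | truth$poised)
  if (!length(sel)) {
    return(signal_track(data.frame(chrom = character(), start = integer(),
                                   end = integer(), value = numeric())))
  }
  tmpl <- ifelse(truth$poised[sel], "nodip", "dip")
  rows <- lapply(seq_along(sel), function(j) {
    i <- sel[j]
    v <- shapes[[tmpl[j]]]$values * 60 * scale
    if (catalog$strand[i] == "-") v <- rev(v)
    data.frame(chrom = catalog$chrom[i],
               cell = (catalog$anchor[i] - flank) %/% bin_bp + seq_len(60L) - 1L,
               value = v)
  })
  acc <- do.call(rbind, rows)
  agg <- stats::aggregate(value ~ chrom + cell, data = acc, FUN = sum)
  agg <- agg[agg$cell >= 0, , drop = FALSE]
  agg <- agg[order(agg$chrom, agg$cell), , drop = FALSE]
  signal_track(data.frame(chrom = agg$chrom,
                          start = as.integer(agg$cell * bin_bp),
                          end = as.integer((agg$cell + 1L) * bin_bp),
                          value = agg$value))
}

#' Simulate a complete synthetic dataset
#'
#' One call producing genome, RTSS catalog, expression matrix, planted truth,
#' per-mark reads and peaks, and a nucleosome track, with per-stage seeds
#' derived from the master seed. The defaults define the package's reference
#' study conditions: 2 chromosomes of 25 Mbp, 300 genes, 2000 RTSSs, 100
#' samples, a 6-active-mark panel plus Pol II, 10 planted metaclusters and a
#' 10% poised fraction among repressed RTSSs.
#'
#' @param n_rtss,S,n_genes,n_chroms,chrom_length scale parameters.
#' @param active_marks active-mark panel (default 6 marks).
#' @param class_fractions see [generate_rtss_set()].
#' @param threshold expressed-class tag threshold (default 5).
#' @param n_meta,poised_fraction,neighborhood_sd,cluster_sd,nb_size
#'   expression/truth model parameters, see [generate_rtss_set()].
#' @param depth,poised_depth,polII_depth,polII_depth_poised,noise_rate,shift
#'   read model parameters, see [generate_chip_reads()].
#' @param seed master seed.
#' @return a `tss_simulation` list with elements `genome`, `catalog`, `expr`,
#'   `truth`, `reads`, `peaks`, `nucleosome`, `archetypes`, `panel`, `params`.
#' @export
simulate_dataset <- function(n_rtss = 2000L, S = 100L, n_genes = 300L,
                             n_chroms = 2L, chrom_length = 25e6,
                             active_marks = c("DNaseHS", "H2AZ", "H3K4me3",
                                              "H3K27ac", "H3K4me1",
                                              "H3K36me3"),
                             class_fractions = default_class_fractions(),
                             threshold = 5L, n_meta = 10L,
                             poised_fraction = 0.1, neighborhood_sd = 0.5,
                             cluster_sd = 0.7, nb_size = 5, depth = 500L,
                             poised_depth = 300L, polII_depth = 600L,
                             polII_depth_poised = 250L, noise_rate = 5,
                             shift = 100L, seed = 1L) {
  genome <- generate_genome(n_chroms, chrom_length, n_genes,
                            seed = derive_stage_seed(seed, "genome"))
  rtss <- generate_rtss_set(genome, n_rtss, class_fractions, S = S,
                            threshold = threshold, n_meta = n_meta,
                            poised_fraction = poised_fraction,
                            neighborhood_sd = neighborhood_sd,
                            cluster_sd = cluster_sd, nb_size = nb_size,
                            seed = derive_stage_seed(seed, "rtss"))
  arch <- metacluster_archetypes(active_marks, n_meta)
  chip <- generate_chip_reads(rtss$truth, rtss$catalog, genome$chrom_sizes,
                              active_marks, archetypes = arch, depth = depth,
                              poised_depth = poised_depth,
                              polII_depth = polII_depth,
                              polII_depth_poised = polII_depth_poised,
                              noise_rate = noise_rate, shift = shift,
                              seed = derive_stage_seed(seed, "chip"))
  nuc <- generate_nucleosome_track(rtss$truth, rtss$catalog,
                                   seed = derive_stage_seed(seed, "nucleosome"))
  structure(
    list(genome = genome, catalog = rtss$catalog, expr = rtss$expr,
         truth = rtss$truth, reads = chip$reads, peaks = chip$peaks,
         nucleosome = nuc, archetypes = arch,
         panel = list(active = active_marks, polII = "PolII"),
         params = list(n_rtss = n_rtss, S = S, threshold = threshold,
                       n_meta = n_meta, poised_fraction = poised_fraction,
                       depth = depth, noise_rate = noise_rate, shift = shift,
                       seed = seed)),
    class = "tss_simulation"
  )
}

#' @export
print.tss_simulation <- function(x, ...) {
  cat("Synthetic TSS/chromatin dataset\n")
  cat("  RTSSs:", nrow(x$catalog), "| samples:", ncol(x$expr),
      "| genes:", nrow(x$genome$genes), "\n")
  cat("  marks:", paste(c(x$panel$active, x$panel$polII), collapse = ", "), "\n")
  tab <- table(x$truth$expression_class)
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "| poised:", sum(x$truth$poised), "\n")
  invisible(x)
}

#' Write a planted-truth table as TSV
#' @param truth truth data.frame.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  data.table::fwrite(truth, path, sep = "\t")
  invisible(path)
}
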