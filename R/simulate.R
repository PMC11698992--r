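#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' study conditions of the transcriptome this package targets: ~73/11/16%
#' leaderless / short-leader / leadered mRNAs, SD-signal rates of 9/169 and
#' 7/169 (GGAGG, UGAGG) among leadered proximal cistrons and 72/879 and
#' 47/879 among distal cistrons, and a 27/1/3/1 mixture of 16S rRNA 3'-end
#' variants over 32 circularization clones.
#'
#' @param seed Root seed; fixes every output byte-identically. Per-component
#'   sub-seeds are derived from it, so adding one generator does not perturb
#'   the others.
#' @param n_tus Number of transcription units.
#' @param leader_class_props Proportions of leaderless / short_leader /
#'   leadered proximal cistrons (sum to 1).
#' @param leader_class_counts Optional exact counts per class (overrides the
#'   proportions; must sum to `n_tus`).
#' @param operon_size_probs Probabilities of operon sizes 1, 2, 3, ...
#' @param n_distal Optional exact total number of distal cistrons,
#'   distributed evenly across TUs (overrides `operon_size_probs`).
#' @param motifs SD motif set to plant and scan.
#' @param sd_positive_rate Per-stratum named rates of rule-passing plantings
#'   per motif (proximal stratum = leadered proximal cistrons).
#' @param decoy_rate Probability that a non-positive stratum gene receives a
#'   positional decoy: the motif planted with its 5' base outside the rule
#'   window relative to every enumerated start.
#' @param sd_positive_counts,sd_decoy_counts Optional exact per-stratum,
#'   per-motif counts (override the rates).
#' @param exact_counts Deterministic largest-remainder allocation of class
#'   and planting counts instead of per-gene sampling (default `TRUE`).
#' @param width,rule,start_codons,span Scan parameters (see
#'   [scan_sd_signals()]); plantings are placed and verified against them.
#' @param max_leader Cap on generated leadered 5'UTR lengths (nt).
#' @param junction List: `n_reads`, `variant_counts` (exact mixture) or
#'   `variant_props`, `anchor`, `reference_5prime`, `flank` (length range),
#'   `exact_counts`.
#' @param toeprint List: `condition_means` (condition -> c(T, RT)),
#'   `n_per_condition`, `mrnas`, `noise_sd`, `reference_condition`.
#' @return A list of class `tir_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_tus = 1000L,
                       leader_class_props = c(leaderless = 0.73,
                                              short_leader = 0.11,
                                              leadered = 0.16),
                       leader_class_counts = NULL,
                       operon_size_probs = c(0.7, 0.2, 0.1),
                       n_distal = NULL,
                       motifs = sd_motifs_default,
                       sd_positive_rate = list(
                         proximal = c(GGAGG = 9 / 169, TGAGG = 7 / 169),
                         distal = c(GGAGG = 72 / 879, TGAGG = 47 / 879)),
                       decoy_rate = 0.25,
                       sd_positive_counts = NULL,
                       sd_decoy_counts = NULL,
                       exact_counts = TRUE,
                       width = 30L,
                       rule = c(-18L, -9L),
                       start_codons = c("ATG", "GTG", "TTG"),
                       span = c(-30L, 30L),
                       max_leader = 50L,
                       junction = list(),
                       toeprint = list()) {
  if (!is.null(leader_class_counts) && sum(leader_class_counts) != n_tus) {
    stop("leader_class_counts must sum to n_tus", call. = FALSE)
  }
  if (abs(sum(leader_class_props) - 1) > 1e-8) {
    stop("leader_class_props must sum to 1", call. = FALSE)
  }
  # shallow merge: a user-supplied sub-list entry replaces the default whole
  merge_opts <- function(base, user) {
    for (nm in names(user)) base[[nm]] <- user[[nm]]
    base
  }
  jc <- merge_opts(list(
    n_reads = 32L,
    variant_counts = c(CCUCC = 27L, CCUCA = 1L, CCUC = 3L, CCU = 1L),
    variant_props = NULL,
    anchor = "AAUCC",
    reference_5prime = "AAUCCGGUUGAUCCUGCCGG",
    flank = c(20L, 40L),
    exact_counts = TRUE
  ), junction)
  tp <- merge_opts(list(
    condition_means = list(
      monophosphate = c(T = 70, RT = 30),
      triphosphate = c(T = 55, RT = 45),
      hydroxyl = c(T = 30, RT = 70)
    ),
    n_per_condition = 3L,
    mrnas = c("aIF2beta", "MAP"),
    noise_sd = 4,
    reference_condition = "monophosphate"
  ), toeprint)
  structure(list(
    seed = as.integer(seed), n_tus = as.integer(n_tus),
    leader_class_props = leader_class_props,
    leader_class_counts = leader_class_counts,
    operon_size_probs = operon_size_probs, n_distal = n_distal,
    motifs = check_motifs(motifs),
    sd_positive_rate = sd_positive_rate, decoy_rate = decoy_rate,
    sd_positive_counts = sd_positive_counts,
    sd_decoy_counts = sd_decoy_counts,
    exact_counts = isTRUE(exact_counts),
    width = as.integer(width), rule = as.integer(rule),
    start_codons = start_codons, span = as.integer(span),
    max_leader = as.integer(max_leader),
    junction = jc, toeprint = tp
  ), class = "tir_sim_config")
}

# Largest-remainder allocation of n items to proportions p.
alloc_counts <- function(n, p) {
  p <- p / sum(p)
  base <- floor(p * n)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- p * n - base
    top <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[top] <- base[top] + 1
  }
  as.integer(base)
}

random_seq <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_cds <- function(n_internal_codons) {
  paste0("ATG", random_seq(3L * n_internal_codons), "TAA")
}

`substr_replace` <- function(x, start, value) {
  substr(x, start, start + nchar(value) - 1L) <- value
  x
}

# Verify one gene of a candidate TU against the real scan machinery:
#  - "none":     upstream window free of every motif
#  - "positive": exactly the planted occurrence, and the gene is flagged
#  - "decoy":    exactly the planted occurrence, and the gene is NOT flagged
verify_planting <- function(genome, gene, plant, config) {
  w <- extract_upstream_window(genome, gene, width = config$width)
  hits <- find_motif_occurrences(w, config$motifs)
  if (plant$type == "none") return(nrow(hits) == 0L)
  if (nrow(hits) != 1L || hits$motif != plant$motif ||
      hits$offset_5prime != plant$offset) {
    return(FALSE)
  }
  refs <- enumerate_reference_starts(genome, gene,
                                     start_codons = config$start_codons,
                                     span = config$span)
  calls <- call_sd_signals(hits, refs, rule = config$rule,
                           gene_id = gene$gene_id)
  flagged <- any(calls$passes_rule)
  if (plant$type == "positive") flagged else !flagged
}

#' Generate a synthetic genome with transcription units and planted SD truth
#'
#' Builds one contig per transcription unit (random strand): an upstream pad,
#' the 5'UTR drawn to realize the configured leader-class partition, then the
#' cistrons separated by intergenic gaps. SD-positive genes receive their
#' motif with the 5' base uniform in the rule window relative to the
#' annotated start; decoy genes receive it at an offset outside the window
#' relative to every enumerated start; all other upstream windows are kept
#' motif-free by rejection resampling (hard iteration cap).
#'
#' @param config A [sim_config()].
#' @param max_tries Rejection-sampling cap per transcription unit.
#' @return List with `genome` (named character vector), `genes`, `tus` and
#'   `truth` (per-gene: role, leader length/class, planted motif and offset).
#' @export
generate_genome_and_tus <- function(config, max_tries = 200L) {
  stopifnot(inherits(config, "tir_sim_config"))
  set.seed(sub_seed(config$seed, 1L))
  n <- config$n_tus
  classes <- names(config$leader_class_props)

  cls_counts <- if (!is.null(config$leader_class_counts)) {
    as.integer(config$leader_class_counts[classes])
  } else if (config$exact_counts) {
    alloc_counts(n, config$leader_class_props)
  } else {
    as.integer(table(factor(sample(classes, n, replace = TRUE,
                                   prob = config$leader_class_props),
                            levels = classes)))
  }
  tu_class <- sample(rep(classes, cls_counts))

  n_dist_per_tu <- if (!is.null(config$n_distal)) {
    nd <- as.integer(config$n_distal)
    base <- rep(nd %/% n, n)
    extra <- nd %% n
    if (extra > 0) {
      idx <- sample.int(n, extra)
      base[idx] <- base[idx] + 1L
    }
    base
  } else {
    sizes <- sample(seq_along(config$operon_size_probs), n, replace = TRUE,
                    prob = config$operon_size_probs)
    sizes - 1L
  }

  # gene bookkeeping before sequence construction
  tu_ids <- sprintf("tu%04d", seq_len(n))
  gene_tab <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- 1L + n_dist_per_tu[i]
    data.frame(gene_id = sprintf("%s_g%d", tu_ids[i], seq_len(k)),
               tu = i, cistron = seq_len(k),
               role = c("proximal", rep("distal", k - 1L)),
               stringsAsFactors = FALSE)
  }))

  leadered_prox <- gene_tab$gene_id[gene_tab$role == "proximal" &
                                      tu_class[gene_tab$tu] == "leadered"]
  distal <- gene_tab$gene_id[gene_tab$role == "distal"]
  strata <- list(proximal = leadered_prox, distal = distal)

  plant_of <- setNames(rep("none", nrow(gene_tab)), gene_tab$gene_id)
  motif_of <- setNames(rep(NA_character_, nrow(gene_tab)), gene_tab$gene_id)
  lookup0 <- function(lst, s, m) {
    x <- lst[[s]]
    if (!is.null(x) && m %in% names(x)) as.numeric(x[[m]]) else 0
  }
  for (s in names(strata)) {
    pool <- strata[[s]]
    for (m in config$motifs) {
      n_pos <- if (!is.null(config$sd_positive_counts)) {
        as.integer(lookup0(config$sd_positive_counts, s, m))
      } else if (config$exact_counts) {
        as.integer(round(length(strata[[s]]) *
                           lookup0(config$sd_positive_rate, s, m)))
      } else {
        stats::rbinom(1L, length(pool), lookup0(config$sd_positive_rate, s, m))
      }
      n_dec <- if (!is.null(config$sd_decoy_counts)) {
        as.integer(lookup0(config$sd_decoy_counts, s, m))
      } else if (config$exact_counts) {
        as.integer(round(length(strata[[s]]) * config$decoy_rate /
                           length(config$motifs)))
      } else {
        stats::rbinom(1L, length(pool), config$decoy_rate / length(config$motifs))
      }
      if (n_pos + n_dec > length(pool)) {
        stop("infeasible config: stratum '", s, "' has ", length(strata[[s]]),
             " genes but ", n_pos + n_dec, " plantings requested for motif ", m,
             call. = FALSE)
      }
      if (n_pos + n_dec > 0L) {
        pick <- sample(pool, n_pos + n_dec)
        pool <- setdiff(pool, pick)
        if (n_pos > 0L) {
          plant_of[pick[seq_len(n_pos)]] <- "positive"
          motif_of[pick[seq_len(n_pos)]] <- m
        }
        if (n_dec > 0L) {
          plant_of[pick[n_pos + seq_len(n_dec)]] <- "decoy"
          motif_of[pick[n_pos + seq_len(n_dec)]] <- m
        }
      }
    }
  }

  pad <- config$width + 10L
  rmin <- config$rule[1]; rmax <- config$rule[2]

  genome <- character(n)
  gene_rows <- vector("list", n)
  tu_rows <- vector("list", n)
  truth_rows <- vector("list", n)

  for (i in seq_len(n)) {
    k <- 1L + n_dist_per_tu[i]
    ids <- gene_tab$gene_id[gene_tab$tu == i]
    leader <- switch(tu_class[i],
                     leaderless = sample(0:5, 1L),
                     short_leader = sample(6:10, 1L),
                     leadered = sample(11:config$max_leader, 1L))
    strand <- sample(c("+", "-"), 1L)
    n_codons <- sample(10:40, k, replace = TRUE)
    gaps <- if (k > 1L) sample((config$width + 6L):(config$width + 30L),
                               k - 1L, replace = TRUE) else integer(0)

    ok <- FALSE
    for (try in seq_len(max_tries)) {
      sense <- random_seq(pad + leader)
      starts_sense <- integer(k)
      for (j in seq_len(k)) {
        starts_sense[j] <- nchar(sense) + 1L
        sense <- paste0(sense, random_cds(n_codons[j]))
        if (j < k) sense <- paste0(sense, random_seq(gaps[j]))
      }
      sense <- paste0(sense, random_seq(10L))

      plant_offsets <- rep(NA_integer_, k)
      for (j in seq_len(k)) {
        pt <- plant_of[[ids[j]]]
        if (pt == "none") next
        m <- motif_of[[ids[j]]]
        wm <- nchar(m)
        if (pt == "positive") {
          o <- sample(rmin:rmax, 1L)
        } else {
          cand <- setdiff(seq(-config$width, -wm), rmin:rmax)
          o <- sample(cand, 1L)
        }
        plant_offsets[j] <- o
        sense <- substr_replace(sense, starts_sense[j] + o, m)
      }

      nlen <- nchar(sense)
      contig <- if (strand == "+") sense else revcomp(sense)
      tss_sense <- pad + 1L
      cds_len <- 3L * (n_codons + 2L)
      grows <- data.frame(
        gene_id = ids, contig = tu_ids[i], strand = strand,
        cds_start = if (strand == "+") starts_sense
                    else nlen - (starts_sense + cds_len - 1L) + 1L,
        cds_end = if (strand == "+") starts_sense + cds_len - 1L
                  else nlen - starts_sense + 1L,
        stringsAsFactors = FALSE
      )
      gtmp <- setNames(contig, tu_ids[i])
      all_ok <- TRUE
      for (j in seq_len(k)) {
        pl <- list(type = plant_of[[ids[j]]], motif = motif_of[[ids[j]]],
                   offset = plant_offsets[j])
        if (!verify_planting(gtmp, grows[j, ], pl, config)) { all_ok <- FALSE; break }
      }
      if (all_ok) {
        genome[i] <- contig
        gene_rows[[i]] <- grows
        tu_rows[[i]] <- data.frame(
          tu_id = tu_ids[i], contig = tu_ids[i], strand = strand,
          tss = if (strand == "+") tss_sense else nlen - tss_sense + 1L,
          genes = paste(ids, collapse = ","), stringsAsFactors = FALSE
        )
        truth_rows[[i]] <- data.frame(
          gene_id = ids, tu_id = tu_ids[i],
          role = c("proximal", rep("distal", k - 1L)),
          leader_length = c(leader, rep(NA_integer_, k - 1L)),
          leader_class = c(tu_class[i], rep(NA_character_, k - 1L)),
          planted = unname(plant_of[ids]),
          planted_motif = unname(motif_of[ids]),
          planted_offset = plant_offsets,
          stringsAsFactors = FALSE
        )
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not realize plantings for ", tu_ids[i], " within ",
           max_tries, " attempts (infeasible config?)", call. = FALSE)
    }
  }

  names(genome) <- tu_ids
  list(genome = genome,
       genes = do.call(rbind, gene_rows),
       tus = do.call(rbind, tu_rows),
       truth = do.call(rbind, truth_rows))
}

#' Generate synthetic circularized-rRNA junction reads
#'
#' Each read is a random flank, then the chosen 3'-end variant, then a prefix
#' of the 5' region beginning with the anchor — the structure a clone
#' sequenced across the ligation junction shows. With `exact_counts` the
#' variant mixture is allocated deterministically; reads are emitted in
#' shuffled order. Each read is verified to classify back to its planted
#' variant (rejection on the random flank).
#'
#' @param config A [sim_config()] (the `junction` sub-list is used).
#' @param max_tries Rejection cap per read.
#' @return List with `reads` (named character vector, DNA alphabet) and
#'   `truth` (`read_id`, `true_variant`).
#' @export
generate_junction_reads <- function(config, max_tries = 100L) {
  stopifnot(inherits(config, "tir_sim_config"))
  jc <- config$junction
  set.seed(sub_seed(config$seed, 2L))
  catalog <- names(jc$variant_counts) %||% end_variant_catalog
  counts <- if (!is.null(jc$variant_props)) {
    if (jc$exact_counts) {
      setNames(alloc_counts(jc$n_reads, jc$variant_props), names(jc$variant_props))
    } else {
      tab <- table(factor(sample(names(jc$variant_props), jc$n_reads,
                                 replace = TRUE, prob = jc$variant_props),
                          levels = names(jc$variant_props)))
      setNames(as.integer(tab), names(jc$variant_props))
    }
  } else {
    jc$variant_counts
  }
  if (sum(counts) != jc$n_reads) {
    stop("variant counts must sum to n_reads", call. = FALSE)
  }
  ref <- normalize_seq(jc$reference_5prime)
  variants <- rep(names(counts), counts)
  reads <- character(length(variants))
  for (i in seq_along(variants)) {
    v <- normalize_seq(variants[i])
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      flank <- random_seq(sample(jc$flank[1]:jc$flank[2], 1L))
      read <- paste0(flank, v, ref)
      cl <- tryCatch({
        j <- locate_junction(read, jc$anchor, jc$reference_5prime)
        classify_end_variant(read, j, catalog = catalog)
      }, error = function(e) NULL)
      if (!is.null(cl) && cl$variant == variants[i] &&
          cl$junction_index == nchar(flank) + nchar(v)) {
        reads[i] <- read
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not build a clean junction read for variant ",
                  variants[i], call. = FALSE)
  }
  ord <- sample.int(length(reads))
  reads <- reads[ord]
  variants <- variants[ord]
  names(reads) <- sprintf("clone%02d", seq_along(reads))
  list(reads = reads,
       truth = data.frame(read_id = names(reads), true_variant = variants,
                          stringsAsFactors = FALSE))
}

#' Generate a synthetic toeprint lane table
#'
#' Lanes carry Gaussian noise (truncated at 0) around per-condition T and RT
#' means; `noise_sd = 0` reproduces the means exactly.
#'
#' @param config A [sim_config()] (the `toeprint` sub-list is used).
#' @return List with `lanes` (lane table as read by [read_toeprint_table()])
#'   and `truth` (per condition: true means and true percent).
#' @export
generate_toeprint_table <- function(config) {
  stopifnot(inherits(config, "tir_sim_config"))
  tp <- config$toeprint
  set.seed(sub_seed(config$seed, 3L))
  if (any(vapply(tp$condition_means, function(x) any(x < 0) || sum(x) <= 0,
                 logical(1)))) {
    stop("condition means must be non-negative with T + RT > 0", call. = FALSE)
  }
  rows <- list(); trows <- list()
  for (m in tp$mrnas) {
    for (cond in names(tp$condition_means)) {
      mu <- tp$condition_means[[cond]]
      if (tp$n_per_condition < 1L) next
      for (r in seq_len(tp$n_per_condition)) {
        rows[[length(rows) + 1L]] <- data.frame(
          lane_id = sprintf("%s_%s_r%d", m, cond, r),
          condition = cond, mrna = m,
          T = max(0, stats::rnorm(1L, mu[["T"]], tp$noise_sd)),
          RT = max(0, stats::rnorm(1L, mu[["RT"]], tp$noise_sd)),
          stringsAsFactors = FALSE
        )
      }
      trows[[length(trows) + 1L]] <- data.frame(
        mrna = m, condition = cond, true_T = mu[["T"]], true_RT = mu[["RT"]],
        true_percent = 100 * mu[["T"]] / sum(mu), stringsAsFactors = FALSE
      )
    }
  }
  list(lanes = do.call(rbind, rows), truth = do.call(rbind, trows))
}

#' Write a simulated dataset to disk
#'
#' Emits the plain-text files the analysis modules read: `genome.fa`,
#' `genes.tsv`, `tus.tsv`, `junction_reads.fa`, `toeprint.tsv`, plus the
#' ground-truth tables (`truth_*.tsv`).
#'
#' @param sim List with any of `genome`/`genes`/`tus`/`truth` (from
#'   [generate_genome_and_tus()]), `reads` (from [generate_junction_reads()])
#'   and `lanes` (from [generate_toeprint_table()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$genome)) write_fasta(sim$genome, file.path(dir, "genome.fa"))
  if (!is.null(sim$genes)) wtsv(sim$genes, "genes.tsv")
  if (!is.null(sim$tus)) wtsv(sim$tus, "tus.tsv")
  if (!is.null(sim$truth)) wtsv(sim$truth, "truth_genes.tsv")
  if (!is.null(sim$reads)) write_fasta(sim$reads, file.path(dir, "junction_reads.fa"))
  if (!is.null(sim$lanes)) wtsv(sim$lanes, "toeprint.tsv")
  invisible(dir)
}
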