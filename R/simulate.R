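#' Parameters of the metastasis branching-process simulator
#'
#' Defaults are the stated conditions of the simulated world: cells divide
#' at birth rate `b = 0.16` and die at death rate `d = 0.1555` (per day), a
#' dividing cell's daughter successfully colonizes a new site with
#' probability `q_mig = 1e-9`, a division acquires a point mutation with
#' probability `u = 0.145` (5e-10 per basepair over a 45 Mb exome) and a
#' copy-number variant with probability `cnv_rate = 0.001`, and the
#' simulation stops once `m_mets` spatially distinct metastases have reached
#' the detection size `M = 1e8` cells. Sequencing draws a one-million-cell
#' sample per metastasis at the given `purity`, with negative-binomially
#' distributed depth (`mean_depth`; variance twice the mean, i.e. dispersion
#' size = mean) and per-read error `e_seq = 0.5%`. A mutated locus is
#' reported when, in at least one sample, its VAF is at least 5% and it is
#' supported by at least four variant reads (two when the mean depth is 25).
#'
#' @param b,d Birth and death rates; require `0 <= d < b`.
#' @param q_mig Per-division successful colonization probability.
#' @param u Point-mutation probability per division.
#' @param cnv_rate CNV probability per division.
#' @param M Metastasis detection size (cells).
#' @param m_mets Number of metastases to detect and sample.
#' @param purity Neoplastic cell content of each sequenced sample.
#' @param mean_depth Mean sequencing depth.
#' @param nb_size Negative-binomial dispersion (default `mean_depth`, so the
#'   depth variance is twice the mean).
#' @param e_seq Sequencing error rate.
#' @param polyphyletic_count Number of sampled metastases that are mixtures
#'   of two sites (reseeding); 0 = all monophyletic.
#' @param n_founders Number of clonal founder mutations carried by the
#'   initiating cell.
#' @param n_switch Hybrid-simulation switch: sites are simulated cell by
#'   cell up to this size and deterministically afterwards.
#' @param genome_mb Exome size in megabases over which mutations land.
#' @param rng_seed Seed.
#' @param max_retries Retries when the initiating lineage goes extinct.
#' @return A `sim_params` object (validated list).
#' @export
sim_params <- function(b = 0.16, d = 0.1555, q_mig = 1e-9, u = 0.145,
                       cnv_rate = 0.001, M = 1e8, m_mets = 6L,
                       purity = 0.75, mean_depth = 400,
                       nb_size = mean_depth, e_seq = 0.005,
                       polyphyletic_count = 0L, n_founders = 20L,
                       n_switch = 1e4, genome_mb = 45, rng_seed = 1L,
                       max_retries = 100L) {
  if (d < 0 || d >= b) stop("require 0 <= d < b")
  for (pr in c(q_mig, u, cnv_rate, e_seq))
    if (pr < 0 || pr > 1) stop("probabilities must lie in [0,1]")
  if (M < 1) stop("M must be >= 1")
  if (purity <= 0 || purity > 1) stop("purity must lie in (0,1]")
  if (polyphyletic_count > m_mets) stop("polyphyletic_count > m_mets")
  structure(list(b = b, d = d, q_mig = q_mig, u = u, cnv_rate = cnv_rate,
                 M = M, m_mets = as.integer(m_mets), purity = purity,
                 mean_depth = mean_depth, nb_size = nb_size, e_seq = e_seq,
                 polyphyletic_count = as.integer(polyphyletic_count),
                 n_founders = as.integer(n_founders), n_switch = n_switch,
                 genome_mb = genome_mb, rng_seed = as.integer(rng_seed),
                 max_retries = as.integer(max_retries)),
            class = "sim_params")
}

# draw the next deterministic-phase emission time for a site growing as
# n(t) = n_switch * exp(r (t - t_switch)); emissions are an inhomogeneous
# Poisson process with intensity q_mig * b * n(t)
next_emission_time <- function(site, after, params) {
  if (params$q_mig <= 0) return(Inf)
  r <- params$b - params$d
  e1 <- stats::rexp(1L)
  base <- exp(r * (after - site$t_switch))
  fac <- base + e1 * r / (params$q_mig * params$b * params$n_switch)
  site$t_switch + log(fac) / r
}

#' Simulate metastatic progression as a multi-type branching process
#'
#' A single advanced cancer cell (carrying `n_founders` clonal mutations)
#' initiates the primary tumour. Sites grow cell by cell (Gillespie) until
#' `n_switch` cells and deterministically afterwards with frozen clonal
#' composition; emigrating daughters found new sites (metastasis-to-
#' metastasis seeding included) and most such attempts go extinct. Mutations
#' arising after a site passes `n_switch` cannot reach a detectable cell
#' fraction and are only tracked along emigrating founder lineages (Poisson
#' numbers of private clonal mutations). The simulation stops once `m_mets`
#' metastases have reached size `M`; those metastases are the sampled
#' lesions, labelled `M1, M2, ...` in chronological order of seeding.
#'
#' @param params A [sim_params()].
#' @return An object of class `simulated_tumor`: genotype tree (`genotypes`:
#'   id, parent, type 0 = SNV / 1 = CNV / 2 = root, time), `sites` data
#'   frame, `sampled_sites`, `sample_names`, compositions, founder chains,
#'   `t_stop`, and `params`.
#' @export
simulate_tumor <- function(params = sim_params()) {
  set.seed(params$rng_seed)
  for (retry in seq_len(params$max_retries)) {
    out <- try(simulate_tumor_once(params), silent = TRUE)
    if (!inherits(out, "try-error")) return(out)
    if (!grepl("extinct", conditionMessage(attr(out, "condition"))))
      stop(attr(out, "condition"))
  }
  stop("initiating lineage went extinct in every retry")
}

simulate_tumor_once <- function(params) {
  r <- params$b - params$d
  gl <- list()  # genotype chunks: data.frames id/parent/type/time
  # root node + founder mutation chain
  nf <- params$n_founders
  gl[[1L]] <- list(parent = 0:nf, type = c(2L, rep(0L, nf)),
                   time = rep(0, nf + 1L))
  next_id <- nf + 2L
  founder_tip <- nf + 1L

  grow <- function(founder_geno, t0) {
    res <- .grow_site(params$b, params$d, params$u, params$cnv_rate,
                      params$q_mig, as.integer(params$n_switch),
                      as.integer(founder_geno), as.integer(next_id), t0)
    if (length(res$geno_id)) {
      gl[[length(gl) + 1L]] <<- list(parent = res$geno_parent,
                                     type = res$geno_type,
                                     time = res$geno_time)
      next_id <<- res$next_geno_id
    }
    res
  }

  # condition the initiating lineage on survival (extinction probability
  # d/b ~ 0.97 per attempt)
  for (att in seq_len(10000L)) {
    res <- grow(founder_tip, 0)
    if (!res$extinct) break
  }
  if (res$extinct) stop("primary lineage extinct")

  sites <- list(list(id = 1L, parent_site = NA_integer_, t_found = 0,
                     founder_geno = founder_tip, t_switch = res$t_end,
                     comp_geno = res$comp_geno, comp_count = res$comp_count,
                     births = res$births, checkpoints = res$checkpoints,
                     t_detect = Inf, next_emit = NA_real_))
  t_detect_of <- function(t_switch)
    t_switch + max(0, log(params$M / params$n_switch)) / r
  sites[[1L]]$t_detect <- Inf  # primary is never a sampled metastasis
  sites[[1L]]$next_emit <- next_emission_time(sites[[1L]], res$t_end, params)
  stoch_mig <- if (length(res$mig_time)) {
    data.frame(time = res$mig_time, geno = res$mig_geno, site = 1L)
  } else data.frame(time = numeric(0L), geno = integer(0L), site = integer(0L))

  # Any site seeded at time t reaches the detection size no earlier than
  # t + log(M/n_switch)/r (its stochastic phase adds strictly positive
  # time), so emissions later than the m-th candidate detection minus that
  # lag are irrelevant.  Additionally, at most 3*m_mets surviving sites are
  # instantiated: the deterministic-phase lag dominates the detection time,
  # hence later-seeded sites cannot be among the first m detections except
  # with negligible probability (methods vignette).
  det_lag <- max(0, log(params$M / params$n_switch)) / r
  site_cap <- 3L * params$m_mets + 1L
  attempts <- 0L
  repeat {
    attempts <- attempts + 1L
    if (attempts > 2e5) stop("seeding attempt budget exceeded")
    # earliest pending emission (stochastic-phase leftovers or deterministic)
    det_next <- vapply(sites, `[[`, numeric(1L), "next_emit")
    t_s <- if (nrow(stoch_mig)) min(stoch_mig$time) else Inf
    t_e <- min(det_next, t_s)
    if (!is.finite(t_e)) stop("no further seeding possible (q_mig = 0?)")
    dets <- sort(vapply(sites, `[[`, numeric(1L), "t_detect"))
    dets <- dets[is.finite(dets)]
    if (length(dets) >= params$m_mets &&
        (length(sites) >= site_cap ||
         dets[params$m_mets] <= t_e + det_lag)) break

    if (t_s <= min(det_next)) {
      k <- which.min(stoch_mig$time)
      te <- stoch_mig$time[k]; src <- stoch_mig$site[k]
      geno <- stoch_mig$geno[k]
      stoch_mig <- stoch_mig[-k, , drop = FALSE]
    } else {
      src <- which.min(det_next)
      te <- det_next[src]
      s <- sites[[src]]
      sites[[src]]$next_emit <- next_emission_time(s, te, params)
      geno <- sample(s$comp_geno, 1L, prob = s$comp_count)
      # private mutations along the emigrating lineage since the switch
      dt <- te - s$t_switch
      n_snv <- stats::rpois(1L, params$u * params$b * dt)
      n_cnv <- stats::rpois(1L, params$cnv_rate * params$b * dt)
      n_chain <- n_snv + n_cnv
      if (n_chain > 0L) {
        types <- sample(c(rep(0L, n_snv), rep(1L, n_cnv)))
        ids <- next_id + seq_len(n_chain) - 1L
        gl[[length(gl) + 1L]] <- list(
          parent = c(geno, ids[-n_chain]), type = types,
          time = sort(stats::runif(n_chain, s$t_switch, te)))
        next_id <- next_id + n_chain
        geno <- ids[n_chain]
      }
    }
    res <- grow(geno, te)
    if (res$extinct) next
    ns <- list(id = length(sites) + 1L, parent_site = src, t_found = te,
               founder_geno = geno, t_switch = res$t_end,
               comp_geno = res$comp_geno, comp_count = res$comp_count,
               births = res$births, checkpoints = res$checkpoints,
               t_detect = t_detect_of(res$t_end), next_emit = NA_real_)
    ns$next_emit <- next_emission_time(ns, res$t_end, params)
    sites[[length(sites) + 1L]] <- ns
    if (length(res$mig_time)) {
      stoch_mig <- rbind(stoch_mig, data.frame(
        time = res$mig_time, geno = res$mig_geno, site = ns$id))
    }
  }

  dets <- vapply(sites, `[[`, numeric(1L), "t_detect")
  ord <- order(dets)
  sampled <- ord[seq_len(params$m_mets)]
  t_stop <- dets[sampled[params$m_mets]]
  # label metastases in chronological order of seeding
  found_t <- vapply(sites, `[[`, numeric(1L), "t_found")
  sampled <- sampled[order(found_t[sampled])]
  sample_names <- paste0("M", seq_along(sampled))

  G <- list(parent = unlist(lapply(gl, `[[`, "parent")),
            type = unlist(lapply(gl, `[[`, "type")),
            time = unlist(lapply(gl, `[[`, "time")))
  G <- data.frame(id = seq_along(G$parent), parent = G$parent,
                  type = G$type, time = G$time)
  stopifnot(nrow(G) == next_id - 1L)
  sizes <- vapply(sites, function(s) {
    params$n_switch * exp(r * (t_stop - s$t_switch))
  }, numeric(1L))

  structure(list(genotypes = G, sites = sites,
                 sampled_sites = sampled, sample_names = sample_names,
                 site_sizes = sizes, t_stop = t_stop,
                 founder_tip = founder_tip, n_attempts = attempts,
                 params = params),
            class = "simulated_tumor")
}

#' @export
print.simulated_tumor <- function(x, ...) {
  cat(sprintf(paste0("simulated_tumor: %d sites (%d sampled metastases), ",
                     "%d genotype nodes, stop at t = %.1f\n"),
              length(x$sites), length(x$sampled_sites),
              nrow(x$genotypes), x$t_stop))
  invisible(x)
}

# ancestor chain of a genotype id (including itself), root last
ancestor_chain <- function(G, id) {
  out <- integer(0L)
  while (id > 0L) {
    out <- c(out, id)
    id <- G$parent[id]
  }
  out
}

#' In-silico sequencing of the sampled metastases
#'
#' Draws one million cells per sampled metastasis at the configured purity
#' (polyphyletic samples mix cells from two sites proportional to their
#' sizes), computes per-locus variant allele fractions from the clonal
#' composition (adjusting for overlapping copy-number events by event
#' timing), and simulates reads: depth `N ~ NegBin(mean_depth, nb_size)` and
#' variant reads `K ~ Binomial(N, theta(f))` with the sequencing error
#' channel of [theta_channel()]. Only loci detected in at least one sample
#' (VAF >= 5% and >= 4 variant reads; >= 2 when the mean depth is 25) are
#' reported.
#'
#' @param tumor A [simulate_tumor()] result.
#' @param params The [sim_params()] used (defaults to the tumour's).
#' @return List with `matrix` (a [variant_call_matrix()]) and `truth`: cell
#'   fractions, clonal flags, true clades among sampled lesions, the
#'   parental matrix `A` over parsimony-informative mutations, seeding
#'   times, and the mixing partners of polyphyletic samples.
#' @export
sequence_samples <- function(tumor, params = tumor$params) {
  G <- tumor$genotypes
  m <- length(tumor$sampled_sites)
  ncells <- 1e6
  nnode <- nrow(G)

  mix_partner <- rep(NA_integer_, m)
  if (params$polyphyletic_count > 0L) {
    poly <- sample(seq_len(m), params$polyphyletic_count)
    for (i in poly) {
      others <- setdiff(seq_along(tumor$sites), tumor$sampled_sites[i])
      mix_partner[i] <- if (length(others) == 1L) others else
        sample(others, 1L)
    }
  }

  frac <- matrix(0, nnode, m)
  for (i in seq_len(m)) {
    s <- tumor$sites[[tumor$sampled_sites[i]]]
    cnt <- numeric(nnode)
    if (is.na(mix_partner[i])) {
      draw <- stats::rmultinom(1L, ncells, s$comp_count)[, 1L]
      cnt[s$comp_geno] <- cnt[s$comp_geno] + draw
    } else {
      s2 <- tumor$sites[[mix_partner[i]]]
      w <- tumor$site_sizes[c(s$id, s2$id)]
      n1 <- stats::rbinom(1L, ncells, w[1L] / sum(w))
      d1 <- stats::rmultinom(1L, n1, s$comp_count)[, 1L]
      d2 <- stats::rmultinom(1L, ncells - n1, s2$comp_count)[, 1L]
      cnt[s$comp_geno] <- cnt[s$comp_geno] + d1
      cnt[s2$comp_geno] <- cnt[s2$comp_geno] + d2
    }
    frac[, i] <- .accumulate_descendants(G$parent, cnt) / ncells
  }

  present_any <- rowSums(frac) > 0
  snv_nodes <- which(G$type == 0L & present_any)
  cnv_nodes <- which(G$type == 1L & present_any)

  # mutation placement over the exome; CNVs must not overlap along a lineage
  chrom_mb <- params$genome_mb / 22
  ann <- assign_loci(G, snv_nodes, cnv_nodes, chrom_mb)

  vaf_num <- frac[snv_nodes, , drop = FALSE]
  vaf_den <- matrix(2, length(snv_nodes), m)
  if (nrow(ann$cnv)) {
    for (ci in seq_len(nrow(ann$cnv))) {
      cn <- ann$cnv$node[ci]
      cfrac <- frac[cn, ]
      hit <- which(ann$snv$chrom == ann$cnv$chrom[ci] &
                     ann$snv$pos >= ann$cnv$start[ci] &
                     ann$snv$pos <= ann$cnv$end[ci])
      if (!length(hit)) next
      sgn <- if (ann$cnv$gain[ci]) 1 else -1
      anc <- ancestor_chain(G, cn)
      for (si in hit) {
        vaf_den[si, ] <- pmax(vaf_den[si, ] + sgn * cfrac, 1e-9)
        if (ann$snv$hap[si] == ann$cnv$hap[ci] &&
            snv_nodes[si] %in% anc) {
          # CNV is a descendant of the mutation: variant copies change
          vaf_num[si, ] <- pmax(vaf_num[si, ] + sgn * cfrac, 0)
        }
      }
    }
  }
  gam <- params$purity
  f <- gam * vaf_num / (gam * vaf_den + (1 - gam) * 2)

  nl <- length(snv_nodes)
  th <- theta_channel(f, params$e_seq)
  N <- matrix(stats::rnbinom(nl * m, size = params$nb_size,
                             mu = params$mean_depth), nl, m)
  K <- matrix(stats::rbinom(nl * m, as.vector(N), as.vector(th)), nl, m)
  min_reads <- if (params$mean_depth <= 25) 2L else 4L
  detected_cell <- K >= min_reads & K >= 0.05 * N
  keep <- rowSums(detected_cell) > 0L

  ids <- snv_nodes[keep]
  rn <- paste0("mut", ids)
  Kk <- K[keep, , drop = FALSE]; Nk <- N[keep, , drop = FALSE]
  dimnames(Kk) <- dimnames(Nk) <- list(rn, tumor$sample_names)
  vcm <- variant_call_matrix(
    Kk, Nk, purity = stats::setNames(rep(gam, m), tumor$sample_names),
    patient_id = "simulated", variants = ann$snv[match(ids, ann$snv$node), ])

  clonal <- frac[snv_nodes, , drop = FALSE] >= 1 - 1e-9
  rownames(clonal) <- paste0("mut", snv_nodes)
  colnames(clonal) <- tumor$sample_names
  fr <- frac[snv_nodes, , drop = FALSE]
  dimnames(fr) <- dimnames(clonal)

  truth <- list(
    mutation_nodes = snv_nodes,
    frac = fr, clonal = clonal,
    detected = rn,
    clades = true_clades(tumor),
    A = true_mutation_matrix(clonal),
    mix_partner = mix_partner,
    seeding_times = vapply(tumor$sites[tumor$sampled_sites], `[[`,
                           numeric(1L), "t_found"))
  list(matrix = vcm, truth = truth)
}

assign_loci <- function(G, snv_nodes, cnv_nodes, chrom_mb) {
  ns <- length(snv_nodes)
  snv <- data.frame(node = snv_nodes,
                    chrom = sample.int(22L, ns, replace = TRUE),
                    pos = round(stats::runif(ns, 1, chrom_mb * 1e6)),
                    hap = sample.int(2L, ns, replace = TRUE))
  nc <- length(cnv_nodes)
  cnv <- data.frame(node = integer(0L), chrom = integer(0L),
                    start = numeric(0L), end = numeric(0L),
                    hap = integer(0L), gain = logical(0L))
  if (nc) {
    cnv <- data.frame(node = cnv_nodes,
                      chrom = sample.int(22L, nc, replace = TRUE),
                      start = NA_real_, end = NA_real_,
                      hap = sample.int(2L, nc, replace = TRUE),
                      gain = stats::runif(nc) < 0.5)
    for (i in seq_len(nc)) {
      anc <- intersect(ancestor_chain(G, cnv_nodes[i]), cnv_nodes)
      anc <- setdiff(anc, cnv_nodes[i])
      prev <- cnv[match(anc, cnv$node), , drop = FALSE]
      prev <- prev[!is.na(prev$start) & prev$chrom == cnv$chrom[i] &
                     prev$hap == cnv$hap[i], , drop = FALSE]
      for (try in 1:20) {
        len <- stats::rlnorm(1L, log(1e5), 1)
        st <- stats::runif(1L, 1, chrom_mb * 1e6)
        en <- min(st + len, chrom_mb * 1e6)
        if (!nrow(prev) || all(en < prev$start | st > prev$end)) {
          cnv$start[i] <- st; cnv$end[i] <- en
          break
        }
      }
    }
    cnv <- cnv[!is.na(cnv$start), , drop = FALSE]
  }
  list(snv = snv, cnv = cnv)
}

#' True coalescent clades among the sampled metastases
#'
#' Derived from the genotype ancestry of each sampled lesion's founder
#' lineage: every genotype node shared by at least two but not all founder
#' chains defines a coalescent event (the root clade is excluded).
#'
#' @param tumor A [simulate_tumor()] result.
#' @return List of character vectors of sample names.
#' @export
true_clades <- function(tumor) {
  G <- tumor$genotypes
  chains <- lapply(tumor$sampled_sites, function(sid) {
    ancestor_chain(G, tumor$sites[[sid]]$founder_geno)
  })
  m <- length(chains)
  nodes <- unique(unlist(chains))
  member <- vapply(chains, function(ch) nodes %in% ch, logical(length(nodes)))
  member <- matrix(member, nrow = length(nodes))
  sets <- unique(apply(member, 1L, function(row) {
    paste(sort(tumor$sample_names[row]), collapse = "\r")
  }))
  sets <- strsplit(sets, "\r", fixed = TRUE)
  sets[vapply(sets, length, integer(1L)) >= 2L &
         vapply(sets, length, integer(1L)) < m]
}

#' True parental matrix over parsimony-informative mutations
#'
#' For mutations clonal in at least two but not all sampled lesions, the
#' `k x k` matrix `A` has `A[i,j] = 1` when mutation `i` is parental to `j`
#' (its clonal sample set strictly contains `j`'s), `0.5` when both sit on
#' the same branch (identical clonal sample sets, where the ordering is not
#' required), and `0` otherwise.
#'
#' @param clonal Logical matrix (mutations x samples) of clonal presence.
#' @return Numeric matrix with mutation names as dimnames.
#' @export
true_mutation_matrix <- function(clonal) {
  cnt <- rowSums(clonal)
  info <- which(cnt >= 2L & cnt < ncol(clonal))
  k <- length(info)
  A <- matrix(0, k, k, dimnames = list(rownames(clonal)[info],
                                       rownames(clonal)[info]))
  if (k < 2L) return(A)
  sub <- clonal[info, , drop = FALSE]
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    si <- sub[i, ]; sj <- sub[j, ]
    if (all(sj <= si)) {
      A[i, j] <- if (all(si == sj)) 0.5 else 1
    }
  }
  A
}
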