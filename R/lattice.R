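# The spatial environment: a rectangular lattice of sites holding per-site
# metabolite amounts, with diffusion, distal advection, pulsed feeding,
# distal removal, and a well-mixed variant.

#' Lattice geometry and transport parameters
#'
#' The default geometry is a 225 x 8 lattice of 2 x 2 mm sites (a 45 x 1.6
#' cm infant colon, 90 mL total, 0.05 mL per site), a 180 s timestep, two
#' diffusion substeps moving 14.25% of each site's content to each of the
#' four nearest neighbours, and advection of one column per timestep. The
#' coarser `"112x4"` and finer `"450x16"` variants rescale the substeps and
#' advection so the effective diffusion (cm^2/s) and advection speed (mm
#' per timestep) are unchanged.
#'
#' @param variant `"225x8"` (default), `"112x4"`, `"450x16"`, or `"custom"`.
#' @param width,height,site_side_mm,site_volume_ml Only for
#'   `variant = "custom"`: lattice dimensions, site side (mm) and volume.
#' @return An object of class `gut_lattice`.
#' @export
lattice_geometry <- function(variant = c("225x8", "112x4", "450x16", "custom"),
                             width = NULL, height = NULL,
                             site_side_mm = 2, site_volume_ml = 0.05) {
  variant <- match.arg(variant)
  geo <- switch(variant,
    "225x8" = list(width = 225, height = 8, site_side_mm = 2,
                   n_substeps = 2, substep_fraction = 0.1425,
                   advect_cols = 1, advect_every = 1,
                   site_volume_ml = 90 / (225 * 8)),
    "112x4" = list(width = 112, height = 4, site_side_mm = 4,
                   n_substeps = 1, substep_fraction = 0.07125,
                   advect_cols = 1, advect_every = 2,
                   site_volume_ml = 90 / (112 * 4)),
    "450x16" = list(width = 450, height = 16, site_side_mm = 1,
                    n_substeps = 8, substep_fraction = 0.1425,
                    advect_cols = 2, advect_every = 1,
                    site_volume_ml = 90 / (450 * 16)),
    "custom" = {
      stopifnot(!is.null(width), !is.null(height))
      # transport follows the site side so that the effective diffusion
      # (cm^2/s) and advection speed (mm per timestep) match the defaults
      tr <- switch(as.character(site_side_mm),
        "1" = list(n_substeps = 8, substep_fraction = 0.1425,
                   advect_cols = 2, advect_every = 1),
        "4" = list(n_substeps = 1, substep_fraction = 0.07125,
                   advect_cols = 1, advect_every = 2),
        list(n_substeps = 2, substep_fraction = 0.1425,
             advect_cols = 1, advect_every = 1)
      )
      c(list(width = width, height = height, site_side_mm = site_side_mm,
             site_volume_ml = site_volume_ml), tr)
    }
  )
  geo$variant <- variant
  geo$timestep_s <- 180
  geo$feed_columns <- 6
  structure(geo, class = "gut_lattice")
}

#' @export
print.gut_lattice <- function(x, ...) {
  cat("<gut_lattice> ", x$width, "x", x$height, " sites of ",
      x$site_side_mm, "x", x$site_side_mm, " mm, ",
      format(x$site_volume_ml, digits = 4), " mL/site, dt = ",
      x$timestep_s, " s\n", sep = "")
  invisible(x)
}

#' Per-site metabolite amounts on a lattice
#'
#' @param lattice A [lattice_geometry()].
#' @param metabolites Character vector of metabolite ids.
#' @param unlimited Metabolites with symbolically infinite supply (water);
#'   they carry no finite amounts and are exempt from conservation checks.
#' @param non_advected Metabolites exempt from advection (oxygen).
#' @return An object of class `metabolite_field`.
#' @export
metabolite_field <- function(lattice, metabolites,
                             unlimited = "h2o(e)", non_advected = "o2(e)") {
  metabolites <- unique(metabolites)
  w <- lattice$width; h <- lattice$height
  deg <- outer(2 - (seq_len(w) %in% c(1, w)), 2 - (seq_len(h) %in% c(1, h)), "+")
  structure(
    list(
      lattice = lattice,
      amounts = array(0, dim = c(length(metabolites), w, h),
                      dimnames = list(metabolites, NULL, NULL)),
      unlimited = intersect(unlimited, metabolites) ,
      non_advected = intersect(non_advected, metabolites),
      deg = array(rep(as.vector(deg), each = length(metabolites)),
                  dim = c(length(metabolites), w, h))
    ),
    class = "metabolite_field"
  )
}

#' @export
print.metabolite_field <- function(x, ...) {
  cat("<metabolite_field> ", dim(x$amounts)[1], " metabolites on ",
      x$lattice$width, "x", x$lattice$height, " sites\n", sep = "")
  invisible(x)
}

#' Diffuse metabolites
#'
#' Applies the lattice's diffusion substeps: in each substep a fraction
#' `substep_fraction` of every site's amount moves to each of the four
#' nearest neighbours. Walls are no-flux (mass that would cross a lateral,
#' proximal or distal wall stays put), so each metabolite's lattice total
#' is conserved exactly; removal at the distal end is a separate step.
#'
#' @param field A [metabolite_field()].
#' @return The diffused field.
#' @export
diffuse <- function(field) {
  p <- field$lattice$substep_fraction
  w <- field$lattice$width; h <- field$lattice$height
  A <- field$amounts
  for (s in seq_len(field$lattice$n_substeps)) {
    inflow <- array(0, dim = dim(A))
    inflow[, 2:w, ] <- inflow[, 2:w, , drop = FALSE] + A[, 1:(w - 1), , drop = FALSE]
    inflow[, 1:(w - 1), ] <- inflow[, 1:(w - 1), , drop = FALSE] + A[, 2:w, , drop = FALSE]
    inflow[, , 2:h] <- inflow[, , 2:h, drop = FALSE] + A[, , 1:(h - 1), drop = FALSE]
    inflow[, , 1:(h - 1)] <- inflow[, , 1:(h - 1), drop = FALSE] + A[, , 2:h, drop = FALSE]
    A <- A - p * A * field$deg + p * inflow
  }
  field$amounts <- A
  field
}

#' Advect metabolites distally
#'
#' Shifts all metabolites except the `non_advected` set (oxygen) by
#' `advect_cols` columns toward the distal end, on timesteps where the
#' lattice's `advect_every` cadence is due. Mass shifted beyond the lattice
#' is removed and reported in the `"removed"` attribute (named per-metabolite
#' totals, umol).
#'
#' @param field A [metabolite_field()].
#' @param t Current timestep (used for the advection cadence).
#' @return The advected field with attribute `"removed"`.
#' @export
advect <- function(field, t = 1) {
  mets <- dimnames(field$amounts)[[1]]
  removed <- setNames(rep(0, length(mets)), mets)
  if (t %% field$lattice$advect_every != 0) {
    attr(field, "removed") <- removed
    return(field)
  }
  k <- field$lattice$advect_cols
  w <- field$lattice$width
  A <- field$amounts
  move <- !(mets %in% field$non_advected)
  out <- A[move, (w - k + 1):w, , drop = FALSE]
  removed[move] <- apply(out, 1, sum)
  A[move, (k + 1):w, ] <- A[move, 1:(w - k), , drop = FALSE]
  A[move, 1:k, ] <- 0
  field$amounts <- A
  attr(field, "removed") <- removed
  field
}

#' Remove metabolites at the most distal column
#'
#' The most distal column is the end of the colon: its contents are removed
#' from the system every timestep.
#'
#' @param field A [metabolite_field()].
#' @return The field with attribute `"removed"` (per-metabolite umol).
#' @export
remove_distal_metabolites <- function(field) {
  w <- field$lattice$width
  removed <- apply(field$amounts[, w, , drop = FALSE], 1, sum)
  field$amounts[, w, ] <- 0
  attr(field, "removed") <- removed
  field
}

#' Feeding schedule
#'
#' Every `period` timesteps (3 h at defaults) the composition is inserted
#' into the first `columns` proximal columns, divided equally over those
#' sites. GOS is inserted as separate DP3/DP4/DP5 fractions (64/28/8% of
#' the dose by default).
#'
#' @param lactose,gos,fl2 umol per feeding of lactose, GOS and
#'   2'-fucosyllactose (Table-2 default dose is 211 umol per nutrient).
#' @param extra Optional named vector of additional nutrients (umol).
#' @param period Timesteps between feedings.
#' @param columns Number of proximal columns fed.
#' @param gos_fractions Mass fractions of the DP3/DP4/DP5 GOS fractions;
#'   must sum to 1.
#' @return An object of class `feed_schedule`.
#' @export
feed_schedule <- function(lactose = 211, gos = 0, fl2 = 0, extra = NULL,
                          period = 60, columns = 6,
                          gos_fractions = c(gos_dp3 = 0.64, gos_dp4 = 0.28,
                                            gos_dp5 = 0.08)) {
  stopifnot(lactose >= 0, gos >= 0, fl2 >= 0, period >= 1)
  if (abs(sum(gos_fractions) - 1) > 1e-9) {
    stop("config error: GOS fractions must sum to 1")
  }
  comp <- c()
  if (lactose > 0) comp["lcts(e)"] <- lactose
  if (fl2 > 0) comp["2fl(e)"] <- fl2
  if (gos > 0) {
    comp[paste0(names(gos_fractions), "(e)")] <- gos * gos_fractions
  }
  if (!is.null(extra)) comp[names(extra)] <- extra
  if (any(comp < 0)) stop("config error: negative feed amounts")
  structure(list(period = period, columns = columns, composition = comp),
            class = "feed_schedule")
}

#' Feed nutrients into the proximal columns
#'
#' Triggers on timesteps `t` with `(t - 1) %% period == 0` (so food is
#' available from the first step); each nutrient's dose is divided equally
#' over the `columns x height` proximal sites.
#'
#' @param field A [metabolite_field()].
#' @param schedule A [feed_schedule()].
#' @param t Current timestep.
#' @return The (possibly) fed field.
#' @export
feed <- function(field, schedule, t) {
  if ((t - 1) %% schedule$period != 0) return(field)
  nc <- schedule$columns
  nsites <- nc * field$lattice$height
  for (m in names(schedule$composition)) {
    if (!m %in% dimnames(field$amounts)[[1]]) {
      stop("config error: feed metabolite '", m, "' not in the field")
    }
    field$amounts[m, 1:nc, ] <- field$amounts[m, 1:nc, ] +
      schedule$composition[[m]] / nsites
  }
  field
}

#' Place initial oxygen
#'
#' Oxygen is present at birth; it is placed once during initialization at
#' `amount` umol per lattice site (0.1 by default; 0 in the no-oxygen
#' variant) and never advects.
#'
#' @param field A [metabolite_field()] containing `"o2(e)"`.
#' @param amount umol per site.
#' @return The field.
#' @export
init_oxygen <- function(field, amount = 0.1) {
  if (amount < 0) stop("config error: initial oxygen must be >= 0")
  if (amount > 0) field$amounts["o2(e)", , ] <- amount
  field
}

#' Redistribute all metabolites equally (well-mixed mode)
#'
#' @param field A [metabolite_field()].
#' @return The field with each metabolite's lattice total divided equally
#'   over all sites.
#' @export
well_mixed_redistribute <- function(field) {
  w <- field$lattice$width; h <- field$lattice$height
  tot <- apply(field$amounts, 1, sum)
  field$amounts <- array(rep(tot / (w * h), w * h),
                         dim = dim(field$amounts),
                         dimnames = dimnames(field$amounts))
  field
}

#' Lattice totals per metabolite
#'
#' @param field A [metabolite_field()].
#' @return Tibble with columns `metabolite`, `umol`.
#' @export
field_totals <- function(field) {
  tibble::tibble(metabolite = dimnames(field$amounts)[[1]],
                 umol = apply(field$amounts, 1, sum))
}

#' Export a field snapshot as a tidy table
#'
#' @param field A [metabolite_field()].
#' @return Tibble with columns `column`, `row`, `metabolite`, `umol`
#'   (nonzero entries only).
#' @export
field_snapshot <- function(field) {
  A <- field$amounts
  nz <- which(A != 0, arr.ind = TRUE)
  tibble::tibble(
    column = nz[, 2], row = nz[, 3],
    metabolite = dimnames(A)[[1]][nz[, 1]],
    umol = A[nz]
  )
}

#' Effective diffusion coefficient of the mixing kernel
#'
#' The per-timestep single-axis displacement variance of the hop kernel
#' (`n_substeps` substeps, each hopping to a given nearest neighbour with
#' probability `substep_fraction`, hop length = site side) divided by
#' `2 * dt`.
#'
#' @param lattice A [lattice_geometry()].
#' @return Diffusion coefficient in cm^2/s.
#' @export
kernel_diffusion_coefficient <- function(lattice = lattice_geometry()) {
  L_cm <- lattice$site_side_mm / 10
  var_per_step <- lattice$n_substeps * 2 * lattice$substep_fraction * L_cm^2
  var_per_step / (2 * lattice$timestep_s)
}

#' Diffusion coefficient measured from tracer dispersion
#'
#' Evolves a point tracer under the lattice's diffusion kernel only (no
#' advection) on a wall-free portion of a large lattice and regresses the
#' displacement variance against time. The kernel acts on the exact
#' probability distribution, so the estimate is deterministic.
#'
#' @param lattice A [lattice_geometry()] supplying the kernel parameters.
#' @param n_steps Number of timesteps to evolve.
#' @return Diffusion coefficient in cm^2/s.
#' @export
tracer_dispersion_coefficient <- function(lattice = lattice_geometry(),
                                          n_steps = 50) {
  span <- 2 * ceiling(sqrt(n_steps * lattice$n_substeps)) + 25
  big <- lattice_geometry("custom", width = 2 * span + 1, height = 2 * span + 1,
                          site_side_mm = lattice$site_side_mm)
  big$n_substeps <- lattice$n_substeps
  big$substep_fraction <- lattice$substep_fraction
  f <- metabolite_field(big, "tracer", unlimited = character(),
                        non_advected = character())
  f$amounts["tracer", span + 1, span + 1] <- 1
  x <- seq_len(big$width) - (span + 1)
  v <- numeric(n_steps)
  for (t in seq_len(n_steps)) {
    f <- diffuse(f)
    px <- apply(f$amounts["tracer", , , drop = FALSE], 2, sum)
    v[t] <- sum(px * x^2) / sum(px)
  }
  slope <- coef(lm(v ~ seq_len(n_steps)))[[2]]
  L_cm <- lattice$site_side_mm / 10
  slope * L_cm^2 / (2 * lattice$timestep_s)
}

#' Mean colonic transit time of a tracer pulse
#'
#' Inserts a unit pulse of an inert tracer into the proximal feed columns
#' and evolves it under the lattice's default diffusion, advection and
#' distal removal; returns the removal-weighted mean exit time.
#'
#' @param lattice A [lattice_geometry()].
#' @param max_steps Safety cap on the number of steps.
#' @param tol Stop once less than this fraction of the pulse remains.
#' @return List with `hours` (mean exit time), `steps` (removal-weighted
#'   mean exit timestep), `steps_run`, and `mass_recovered`.
#' @export
tracer_transit_time <- function(lattice = lattice_geometry(),
                                max_steps = 3000, tol = 1e-9) {
  f <- metabolite_field(lattice, "tracer", unlimited = character(),
                        non_advected = character())
  nc <- lattice$feed_columns
  f$amounts["tracer", 1:nc, ] <- 1 / (nc * lattice$height)
  w_exit <- 0; w_tot <- 0
  t <- 0
  while (t < max_steps) {
    t <- t + 1
    f <- diffuse(f)
    f <- advect(f, t)
    r <- attr(f, "removed")[["tracer"]]
    f <- remove_distal_metabolites(f)
    r <- r + attr(f, "removed")[["tracer"]]
    w_exit <- w_exit + t * r
    w_tot <- w_tot + r
    if (sum(f$amounts) < tol) break
  }
  mean_steps <- w_exit / w_tot
  list(hours = mean_steps * lattice$timestep_s / 3600,
       steps = mean_steps, steps_run = t, mass_recovered = w_tot)
}

#' Diffusion coefficient of the population mixing walk
#'
#' Tracks a lone population under the Kawasaki-style mixing scheme on an
#' otherwise empty lattice and regresses its mean-squared displacement
#' against time.
#'
#' @param lattice A [lattice_geometry()] (site side and timestep).
#' @param side Side of the square test lattice (walls kept far away).
#' @param n_steps,n_walks MSD regression length and number of walks.
#' @param repeats Mixing passes per timestep.
#' @return Diffusion coefficient in cm^2/s.
#' @export
mixing_diffusion_coefficient <- function(lattice = lattice_geometry(),
                                         side = 41, n_steps = 25,
                                         n_walks = 3000, repeats = 1) {
  mid <- (side - 1) %/% 2
  msd <- .kawasaki_msd_cpp(side, side, mid, mid, n_steps, n_walks, repeats)
  tot <- msd[, 1] + msd[, 2]
  slope <- coef(lm(tot ~ seq_len(n_steps)))[[2]]
  L_cm <- lattice$site_side_mm / 10
  slope * L_cm^2 / (4 * lattice$timestep_s)
}
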