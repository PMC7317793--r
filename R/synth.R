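# Seeded generator of synthetic MIAPPE 1.1 datasets covering the hard
# modelling cases of multi-environment trials: multi-local multi-year field
# networks, geolocation-identified forest trees, factorial glasshouse designs,
# time-series observations, sensor-only observation units and crossing
# populations with material-source tracing. Content realism is cosmetic
# (fixed vocabularies, plausible European coordinates); the structure is what
# the generator guarantees: every output validates with zero errors.

with_preserved_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Available synthetic scenarios
#' @return Character vector of scenario tags accepted by [generate_dataset()].
#' @export
synth_scenarios <- function() {
  c("field_network", "forest_geo", "glasshouse_factorial", "time_series",
    "sensor_only", "crossing_population")
}

synth_person_pool <- function() {
  list(
    miappe_person(name = "Ana Ribeiro", email = "ana.ribeiro@example.org",
                  orcid_or_id = "https://orcid.org/0000-0002-0001-0001",
                  affiliation = "Instituto de Tecnologia Verde",
                  role = "principal investigator"),
    miappe_person(name = "Piotr Nowak", email = "p.nowak@example.org",
                  affiliation = "Institute of Plant Genetics",
                  role = "data manager")
  )
}

synth_variable_pool <- function() {
  v <- function(id, name, trait, tacc, method, scale, sacc = NULL,
                time_scale = NULL) {
    miappe_observed_variable(
      id = id, name = name,
      trait = list(name = trait, accession = tacc),
      method = list(name = method,
                    description = paste("Standard protocol for", tolower(trait)),
                    reference = "Field handbook 3rd ed."),
      scale = list(name = scale, accession = sacc), time_scale = time_scale)
  }
  list(
    height = v("var_height", "PH_M_cm", "Plant height", "CO_321:0000020",
               "Measuring tape from ground level", "cm"),
    yield = v("var_yield", "GY_Calc_tha", "Grain yield", "CO_321:0000260",
              "Combine harvest plot weight", "t/ha"),
    heading = v("var_heading", "HD_Jul_d", "Days to heading", "CO_321:0000094",
                "Visual scoring of 50 percent heading", "d"),
    airtemp = v("var_airtemp", "AT_Sensor_C", "Air temperature", "CO_715:0001064",
                "Weather station hourly mean", "degree Celsius",
                time_scale = "date-time"),
    cork = v("var_cork", "CT_Cal_mm", "Cork thickness", "CO_357:1000043",
             "Caliper after bark stripping", "mm"),
    circ = v("var_circ", "TC_M_cm", "Trunk circumference", "CO_357:1000384",
             "Measuring tape at breast height", "cm"),
    canopy = v("var_canopy", "CTemp_IR_C", "Canopy temperature", "CO_321:0000437",
               "Infrared thermometry", "degree Celsius",
               time_scale = "growing degree days"),
    biomass = v("var_biomass", "DW_Bal_g", "Shoot dry weight", "CO_322:0000610",
                "Oven drying and weighing", "g")
  )
}

synth_locations_pool <- function() {
  list(
    list(site = "Clermont-Ferrand", country = "France", lat = 45.777, lon = 3.087),
    list(site = "Poznan", country = "Poland", lat = 52.407, lon = 16.930),
    list(site = "Wageningen", country = "Netherlands", lat = 51.969, lon = 5.665),
    list(site = "Gatersleben", country = "Germany", lat = 51.823, lon = 11.287),
    list(site = "Oeiras", country = "Portugal", lat = 38.697, lon = -9.302),
    list(site = "Ghent", country = "Belgium", lat = 51.054, lon = 3.722)
  )
}

jitter_coord <- function(x, amount = 0.01) round(x + stats::runif(1, -amount, amount), 6)

synth_payload <- function(ous, vars, dates) {
  header <- "observation_unit_id\tvariable_id\ttimestamp\tvalue"
  rows <- character(0)
  for (ou in ous) {
    for (v in vars) {
      rows <- c(rows, sprintf("%s\t%s\t%s\t%.3f", ou, v,
                              dates[1 + (length(rows) %% length(dates))],
                              stats::runif(1, 0, 100)))
    }
  }
  paste(c(header, rows), collapse = "\n")
}

#' Generate a synthetic MIAPPE dataset
#'
#' Deterministically generates a complete, checklist-valid dataset for one of
#' the supported scenarios. The same `(scenario, params, seed)` triple always
#' yields an identical dataset.
#'
#' Scenarios: `field_network` (one study per location spanning several years,
#' biological-material and variable lists shared across studies, plot units
#' under a `study > genotype > plot` hierarchy, a study-level weather-station
#' unit), `forest_geo` (trees identified solely by coordinates, no material
#' source), `glasshouse_factorial` (factors with crossed value combinations
#' over pot units), `time_series` (a growing-degree-days variable and repeated
#' timestamped events), `sensor_only` (an observation unit holding no plant),
#' and `crossing_population` (progeny materials tracing to a parental cross
#' via the material source).
#'
#' @param scenario One of [synth_scenarios()].
#' @param params Named list of scenario-specific counts overriding defaults.
#' @param seed Integer seed.
#' @return A `miappe_dataset`; data-file payload TSVs ride along in its
#'   `payloads` element.
#' @export
generate_dataset <- function(scenario, params = list(), seed = 1L) {
  if (!scenario %in% synth_scenarios()) {
    stop(sprintf("unknown scenario '%s' (known: %s)", scenario,
                 paste(synth_scenarios(), collapse = ", ")), call. = FALSE)
  }
  with_preserved_seed(seed, {
    gen <- switch(scenario,
      field_network = synth_field_network,
      forest_geo = synth_forest_geo,
      glasshouse_factorial = synth_glasshouse_factorial,
      time_series = synth_time_series,
      sensor_only = synth_sensor_only,
      crossing_population = synth_crossing_population)
    out <- gen(params, seed)
    d <- build_dataset(out$investigation,
                       provenance = list(format = "synth", scenario = scenario,
                                         seed = seed))
    d$payloads <- out$payloads
    d
  })
}

synth_investigation <- function(scenario, seed, title, description, studies,
                                start_year = 2016) {
  miappe_investigation(
    id = sprintf("doi:10.5072/miappe.%s.%d", scenario, seed),
    title = title, description = description,
    submission_date = sprintf("%d-01-15", start_year + 3),
    public_release_date = sprintf("%d-06-01", start_year + 3),
    license = "CC BY 4.0", miappe_version = "1.1",
    publications = "doi:10.5072/paper.0001",
    persons = synth_person_pool(), studies = studies)
}

synth_field_network <- function(params, seed) {
  p <- utils::modifyList(list(locations = 3, years = 2, genotypes = 5,
                              plots_per_genotype = 2, samples_per_study = 2),
                         params)
  locs <- synth_locations_pool()
  vars <- synth_variable_pool()
  shared_vars <- list(vars$height, vars$yield, vars$heading, vars$airtemp)
  bms <- lapply(seq_len(p$genotypes), function(i) {
    miappe_biological_material(
      id = sprintf("FRA040 W-%04d", i),
      organism = ontology_ref("Triticum aestivum", "NCBITaxon:4565"),
      genus = "Triticum", species = "aestivum",
      material_source = material_source(
        id = sprintf("FRA040 MS-%04d", i),
        description = "Gene bank accession of the network panel"))
  })
  factor_vals <- c("high nitrogen input", "low nitrogen input")
  start <- "2016-03-15"
  end <- sprintf("%d-11-02", 2016 + max(p$years, 1) - 1)
  studies <- list()
  payloads <- list()
  for (li in seq_len(p$locations)) {
    loc <- locs[[1 + (li - 1) %% length(locs)]]
    sid <- sprintf("wheat-network-%s", slugify(tolower(loc$site)))
    ous <- list(miappe_observation_unit(
      id = sprintf("%s/station", sid), level = "study",
      spatial_distribution = list(X = "0", Y = "0")))
    k <- 0
    for (gi in seq_len(p$genotypes)) {
      for (pi in seq_len(p$plots_per_genotype)) {
        k <- k + 1
        ous[[length(ous) + 1]] <- miappe_observation_unit(
          id = sprintf("%s/plot-%03d", sid, k), level = "plot",
          biological_material_id = bms[[gi]]$id,
          spatial_distribution = list(block = as.character(1 + (k - 1) %% 2),
                                      X = as.character(k), Y = as.character(gi)),
          factor_values = list("nitrogen input level" =
                                 factor_vals[1 + (k %% 2)]))
      }
    }
    samples <- lapply(seq_len(p$samples_per_study), function(si) {
      miappe_sample(
        id = sprintf("%s/sample-%02d", sid, si),
        observation_unit_id = ous[[1 + si]]$id,
        description = "Flag leaf sampled for protein assay",
        plant_anatomical_entity = ontology_ref("leaf", "PO:0025034"),
        plant_structure_development_stage = ontology_ref("flowering stage",
                                                         "PO:0007616"),
        collection_date = "2016-06-20T10:30:00Z",
        external_id = sprintf("SAMEA%07d", 1000000 + li * 100 + si))
    })
    df <- miappe_data_file(
      link = sprintf("data_%s.tsv", slugify(sid)),
      description = "Plot and station level observations for this study",
      version = "1.0")
    payloads[[df$link]] <- synth_payload(
      vapply(ous, function(o) o$id, character(1)),
      vapply(shared_vars, function(v) v$id, character(1)),
      c("2016-06-01", "2016-07-01"))
    studies[[length(studies) + 1]] <- miappe_study(
      id = sid,
      title = sprintf("Wheat network trial at %s", loc$site),
      description = "Multi-year nitrogen response trial of a shared panel",
      start_date = start, end_date = end,
      contact_institution = "Institut du Reseau Ble",
      location = list(country = loc$country, site_name = loc$site,
                      geo = geo_point(jitter_coord(loc$lat),
                                      jitter_coord(loc$lon), 120)),
      experimental_design = list(
        description = "Randomised complete block with two blocks",
        type = ontology_ref("complete block design", "CO_715:0000145")),
      growth_facility = list(description = "Open field",
                             type = ontology_ref("field environment",
                                                 "CO_715:0000162")),
      cultural_practices = "Conventional tillage and standard weed control",
      observation_unit_level_hierarchy = c("study", "genotype", "plot"),
      data_files = list(df), biological_materials = bms,
      environments = list(
        miappe_environment("sowing density", "300 seeds per square metre"),
        miappe_environment("rooting medium", "field soil")),
      factors = list(miappe_factor(
        type = ontology_ref("nitrogen input level", "CO_715:0000252"),
        description = "Contrasted nitrogen fertilisation regimes",
        values = factor_vals)),
      events = list(
        miappe_event(type = ontology_ref("sowing", "CO_715:0000007"),
                     description = "Mechanical sowing of all plots",
                     date = start),
        miappe_event(type = ontology_ref("fertiliser application",
                                         "CO_715:0000011"),
                     description = "Nitrogen top dressing",
                     date = "2016-04-20"),
        miappe_event(type = ontology_ref("fertiliser application",
                                         "CO_715:0000011"),
                     description = "Nitrogen top dressing",
                     date = "2016-05-18")),
      observation_units = ous, samples = samples,
      observed_variables = shared_vars)
  }
  inv <- synth_investigation(
    "field_network", seed, "European wheat nitrogen field network",
    "Multi-local multi-year field phenotyping network with shared germplasm",
    studies)
  list(investigation = inv, payloads = payloads)
}

synth_forest_geo <- function(params, seed) {
  p <- utils::modifyList(list(trees = 10), params)
  vars <- synth_variable_pool()
  sid <- "cork-oak-stand-alentejo"
  bms <- lapply(seq_len(p$trees), function(i) {
    miappe_biological_material(
      id = sprintf("QSUBER-TREE-%03d", i),
      organism = ontology_ref("Quercus suber", "NCBITaxon:58331"),
      genus = "Quercus", species = "suber",
      geo = geo_point(jitter_coord(38.71, 0.05), jitter_coord(-8.95, 0.05),
                      round(stats::runif(1, 150, 240)),
                      coordinates_uncertainty = 4))
  })
  ous <- lapply(bms, function(bm) {
    miappe_observation_unit(
      id = sprintf("%s/%s", sid, tolower(bm$id)), level = "plant",
      biological_material_id = bm$id)
  })
  df <- miappe_data_file(link = "data_cork_oak.tsv",
                         description = "Per-tree cork and growth measurements",
                         version = "1.0")
  payloads <- list()
  payloads[[df$link]] <- synth_payload(
    vapply(ous, function(o) o$id, character(1)),
    c(vars$cork$id, vars$circ$id), c("2017-05-10", "2018-05-12"))
  st <- miappe_study(
    id = sid, title = "Natural cork oak stand survey",
    description = "Forest trees identified by their geographic coordinates",
    start_date = "2017-03-01", end_date = "2018-10-31",
    contact_institution = "Instituto de Tecnologia Verde",
    location = list(country = "Portugal", site_name = "Alentejo stand",
                    geo = geo_point(38.71, -8.95, 180)),
    experimental_design = list(
      description = "Observational survey of a natural population"),
    growth_facility = list(description = "Natural forest stand"),
    observation_unit_level_hierarchy = c("study", "plant"),
    data_files = list(df), biological_materials = bms,
    observation_units = ous,
    observed_variables = list(vars$cork, vars$circ))
  inv <- synth_investigation(
    "forest_geo", seed, "Cork oak natural population phenotyping",
    "Perennial forest trees with coordinate-only material identification",
    list(st), start_year = 2017)
  list(investigation = inv, payloads = payloads)
}

synth_glasshouse_factorial <- function(params, seed) {
  p <- utils::modifyList(list(genotypes = 4, replicates = 2, samples = 4),
                         params)
  vars <- synth_variable_pool()
  sid <- "glasshouse-drought-nitrogen"
  bms <- lapply(seq_len(p$genotypes), function(i) {
    miappe_biological_material(
      id = sprintf("DEU146 HOR-%04d", i),
      organism = ontology_ref("Hordeum vulgare", "NCBITaxon:4513"),
      genus = "Hordeum", species = "vulgare",
      material_source = material_source(
        id = sprintf("DEU146 MS-%04d", i),
        doi = sprintf("doi:10.5072/genebank.%04d", i)))
  })
  drought <- c("rainfed", "irrigated")
  nitrogen <- c("high nitrogen input", "no nitrogen input")
  ous <- list()
  k <- 0
  for (gi in seq_len(p$genotypes)) {
    for (dv in drought) {
      for (nv in nitrogen) {
        for (ri in seq_len(p$replicates)) {
          k <- k + 1
          ous[[length(ous) + 1]] <- miappe_observation_unit(
            id = sprintf("%s/pot-%03d", sid, k), level = "pot",
            biological_material_id = bms[[gi]]$id,
            spatial_distribution = list(lane = as.character(1 + (k - 1) %/% 8),
                                        position = as.character(1 + (k - 1) %% 8)),
            factor_values = list(drought = dv, "nitrogen input level" = nv))
        }
      }
    }
  }
  samples <- lapply(seq_len(min(p$samples, length(ous))), function(si) {
    miappe_sample(
      id = sprintf("%s/sample-%02d", sid, si),
      observation_unit_id = ous[[si]]$id,
      description = "Youngest fully expanded leaf",
      plant_anatomical_entity = ontology_ref("leaf", "PO:0025034"),
      collection_date = "2018-04-12T09:00:00Z")
  })
  df <- miappe_data_file(link = "data_glasshouse.tsv",
                         description = "Imaging-derived biomass and height",
                         version = "2.1")
  payloads <- list()
  payloads[[df$link]] <- synth_payload(
    vapply(ous, function(o) o$id, character(1)),
    c(vars$height$id, vars$biomass$id), c("2018-04-01", "2018-04-15"))
  st <- miappe_study(
    id = sid, title = "Barley drought by nitrogen factorial",
    description = "Automated glasshouse factorial with crossed factors",
    start_date = "2018-02-01", end_date = "2018-05-30",
    contact_institution = "Institute of Plant Genetics",
    location = list(country = "Germany", site_name = "Glasshouse complex 2",
                    geo = geo_point(51.823, 11.287, 112)),
    experimental_design = list(
      description = "Full factorial, randomised within lanes",
      type = ontology_ref("factorial design", "CO_715:0000148")),
    growth_facility = list(
      description = "Automated conveyor glasshouse",
      type = ontology_ref("growth chamber", "CO_715:0000189")),
    cultural_practices = "Daily weighing and target-weight irrigation",
    observation_unit_level_hierarchy = c("study", "pot"),
    data_files = list(df), biological_materials = bms,
    environments = list(
      miappe_environment("target day temperature", "24 degree Celsius"),
      miappe_environment("photoperiod", "16 h light")),
    factors = list(
      miappe_factor(type = ontology_ref("drought", "CO_715:0000277"),
                    description = "Water regime contrast", values = drought),
      miappe_factor(type = ontology_ref("nitrogen input level", "CO_715:0000252"),
                    description = "Nitrogen contrast", values = nitrogen)),
    events = list(
      miappe_event(type = ontology_ref("planting", "CO_715:0000003"),
                   description = "Transfer of seedlings to pots",
                   date = "2018-02-05"),
      miappe_event(type = ontology_ref("fungicide application", "CO_715:0000014"),
                   description = "Preventive fungicide spray",
                   date = "2018-03-02")),
    observation_units = ous, samples = samples,
    observed_variables = list(vars$height, vars$biomass))
  inv <- synth_investigation(
    "glasshouse_factorial", seed, "Barley glasshouse factorial experiment",
    "Controlled-environment factorial with two crossed experimental factors",
    list(st), start_year = 2018)
  list(investigation = inv, payloads = payloads)
}

synth_time_series <- function(params, seed) {
  p <- utils::modifyList(list(plots = 4, event_repeats = 3), params)
  vars <- synth_variable_pool()
  sid <- "maize-time-series"
  bms <- list(miappe_biological_material(
    id = "BEL027 ZM-0001",
    organism = ontology_ref("Zea mays", "NCBITaxon:4577"),
    genus = "Zea", species = "mays"))
  ous <- lapply(seq_len(p$plots), function(i) {
    miappe_observation_unit(
      id = sprintf("%s/plot-%02d", sid, i), level = "plot",
      biological_material_id = bms[[1]]$id,
      spatial_distribution = list(X = as.character(i), Y = "1"))
  })
  events <- lapply(seq_len(p$event_repeats), function(i) {
    miappe_event(type = ontology_ref("irrigation", "CO_715:0000009"),
                 description = "Drip irrigation to field capacity",
                 date = sprintf("2019-06-%02dT06:00:00Z", 4 + 7 * (i - 1)))
  })
  df <- miappe_data_file(link = "data_time_series.tsv",
                         description = "Repeated canopy temperature readings",
                         version = "1.2")
  payloads <- list()
  payloads[[df$link]] <- synth_payload(
    vapply(ous, function(o) o$id, character(1)),
    c(vars$canopy$id, vars$height$id),
    c("2019-06-05", "2019-06-12", "2019-06-19"))
  st <- miappe_study(
    id = sid, title = "Maize canopy temperature time series",
    description = "Single observed variable measured repeatedly on a thermal time scale",
    start_date = "2019-04-20", end_date = "2019-09-30",
    contact_institution = "Plant Systems Biology Unit",
    location = list(country = "Belgium", site_name = "Ghent field platform",
                    geo = geo_point(51.054, 3.722, 9)),
    experimental_design = list(description = "Single genotype monitoring rows"),
    growth_facility = list(description = "Open field"),
    observation_unit_level_hierarchy = c("study", "plot"),
    data_files = list(df), biological_materials = bms,
    events = events, observation_units = ous,
    observed_variables = list(vars$canopy, vars$height))
  inv <- synth_investigation(
    "time_series", seed, "Maize thermal time series investigation",
    "Time-series observations timestamped in growing degree days",
    list(st), start_year = 2019)
  list(investigation = inv, payloads = payloads)
}

synth_sensor_only <- function(params, seed) {
  p <- utils::modifyList(list(plant_plots = 2), params)
  vars <- synth_variable_pool()
  sid <- "field-microclimate"
  bms <- list(miappe_biological_material(
    id = "FRA040 SUN-0001",
    organism = ontology_ref("Helianthus annuus", "NCBITaxon:4232"),
    genus = "Helianthus", species = "annuus"))
  ous <- list(miappe_observation_unit(
    id = sprintf("%s/sensor-mast", sid), level = "study",
    spatial_distribution = list(X = "50", Y = "50")))
  for (i in seq_len(p$plant_plots)) {
    ous[[length(ous) + 1]] <- miappe_observation_unit(
      id = sprintf("%s/plot-%02d", sid, i), level = "plot",
      biological_material_id = bms[[1]]$id,
      spatial_distribution = list(X = as.character(i * 10), Y = "10"))
  }
  df <- miappe_data_file(link = "data_microclimate.tsv",
                         description = "Sensor mast and plot observations",
                         version = "1.0")
  payloads <- list()
  payloads[[df$link]] <- synth_payload(
    vapply(ous, function(o) o$id, character(1)),
    c(vars$airtemp$id, vars$height$id), c("2020-07-01T12:00:00Z"))
  st <- miappe_study(
    id = sid, title = "Field microclimate monitoring",
    description = "A plant-free sensor observation unit in the middle of the field",
    start_date = "2020-04-01", end_date = "2020-10-15",
    contact_institution = "Institut du Reseau Ble",
    location = list(country = "France", site_name = "Montpellier station",
                    geo = geo_point(43.619261, 3.873, 45)),
    experimental_design = list(description = "Monitoring design without treatments"),
    growth_facility = list(description = "Open field"),
    observation_unit_level_hierarchy = c("study", "plot"),
    data_files = list(df), biological_materials = bms,
    observation_units = ous,
    observed_variables = list(vars$airtemp, vars$height))
  inv <- synth_investigation(
    "sensor_only", seed, "Sensor-only observation unit investigation",
    "Environmental observations on an observation unit holding no plant",
    list(st), start_year = 2020)
  list(investigation = inv, payloads = payloads)
}

synth_crossing_population <- function(params, seed) {
  p <- utils::modifyList(list(progeny = 8), params)
  vars <- synth_variable_pool()
  sid <- "poplar-f1-progeny-trial"
  cross <- material_source(
    id = "FRA040 CROSS P0231xP0412",
    description = "F1 cross of two heterozygous poplar parents")
  bms <- lapply(seq_len(p$progeny), function(i) {
    miappe_biological_material(
      id = sprintf("POP-F1-%03d", i),
      organism = ontology_ref("Populus nigra", "NCBITaxon:3691"),
      genus = "Populus", species = "nigra",
      preprocessing = "Cutting rooted in nursery before transplantation",
      material_source = cross)
  })
  ous <- lapply(bms, function(bm) {
    miappe_observation_unit(
      id = sprintf("%s/%s", sid, tolower(bm$id)), level = "plant",
      biological_material_id = bm$id)
  })
  df <- miappe_data_file(link = "data_poplar_progeny.tsv",
                         description = "Growth traits of the F1 progeny",
                         version = "1.0")
  payloads <- list()
  payloads[[df$link]] <- synth_payload(
    vapply(ous, function(o) o$id, character(1)),
    c(vars$circ$id, vars$height$id), c("2017-09-15"))
  st <- miappe_study(
    id = sid, title = "Poplar F1 progeny field trial",
    description = "Progeny of a single cross, each attributed a unique material ID",
    start_date = "2016-11-01", end_date = "2018-11-30",
    contact_institution = "Institut du Reseau Ble",
    location = list(country = "France", site_name = "Orleans nursery",
                    geo = geo_point(47.846, 1.912, 105)),
    experimental_design = list(description = "Single-tree plots in a grid"),
    growth_facility = list(description = "Experimental tree field"),
    observation_unit_level_hierarchy = c("study", "plant"),
    data_files = list(df), biological_materials = bms,
    observation_units = ous,
    observed_variables = list(vars$circ, vars$height))
  inv <- synth_investigation(
    "crossing_population", seed, "Poplar crossing population investigation",
    "Material-source tracing from progeny materials to the parental cross",
    list(st), start_year = 2016)
  list(investigation = inv, payloads = payloads)
}

# -- mutation harness ---------------------------------------------------------

#' Introduce a single checklist defect
#'
#' Returns a copy of the dataset carrying exactly one defect that violates the
#' named rule of [rule_registry()]. Mutators suppress knock-on defects (for
#' example, blanking a biological-material identifier also clears now-dangling
#' optional references to it) so the validation report of the mutated dataset
#' contains the targeted rule and no unrelated errors. This is the test
#' harness for the validator's rule registry.
#'
#' @param dataset A `miappe_dataset` with the section the rule targets.
#' @param rule_id A rule identifier from [rule_registry()].
#' @param seed Integer; reserved for mutators that sample a target record.
#' @return A mutated `miappe_dataset`.
#' @export
mutate_dataset <- function(dataset, rule_id, seed = 1L) {
  registry <- rule_registry()
  if (!rule_id %in% registry$rule_id) {
    stop(sprintf("unknown rule '%s'", rule_id), call. = FALSE)
  }
  inv <- dataset$investigation
  fail <- function(what) {
    stop(sprintf("rule %s is not mutable on this dataset: no %s present",
                 rule_id, what), call. = FALSE)
  }
  # locate the first study index satisfying pred
  study_with <- function(pred, what) {
    for (i in seq_along(inv$studies)) if (pred(inv$studies[[i]])) return(i)
    fail(what)
  }
  if (length(inv$studies %||% list()) == 0 &&
      !rule_id %in% c("CARD-INV-STUDY", "REQ-INV-ID", "FMT-MIAPPE-VERSION")) {
    fail("studies")
  }
  inv <- switch(rule_id,
    "CARD-INV-STUDY" = { inv$studies <- list(); inv },
    "CARD-STU-LOC" = {
      i <- study_with(function(s) TRUE, "studies")
      inv$studies[[i]]$locations <-
        c(inv$studies[[i]]$locations, list(list(country = "Atlantis")))
      inv
    },
    "CARD-SAM-OU" = {
      i <- study_with(function(s) length(s$samples %||% list()) > 0, "samples")
      inv$studies[[i]]$samples[[1]]$observation_unit_id <- NULL
      inv
    },
    "CARD-STU-OU" = {
      i <- study_with(function(s) length(s$observation_units %||% list()) > 0,
                      "observation units")
      inv$studies[[i]]$observation_units <- list()
      inv$studies[[i]]$samples <- list()
      inv$studies[[i]]$events <- lapply(inv$studies[[i]]$events %||% list(),
                                        function(e) { e$affected_units <- NULL; e })
      inv
    },
    "REQ-INV-ID" = { inv$id <- NULL; inv },
    "FMT-MIAPPE-VERSION" = { inv$miappe_version <- "1.0"; inv },
    "REQ-STU-ID" = {
      i <- study_with(function(s) TRUE, "studies")
      inv$studies[[i]]$id <- NULL
      inv
    },
    "REQ-PER-NAME" = ,
    "REQ-PER-ROLE" = {
      field <- if (rule_id == "REQ-PER-NAME") "name" else "role"
      if (length(inv$persons %||% list()) > 0) {
        inv$persons[[1]][[field]] <- NULL
      } else {
        i <- study_with(function(s) length(s$persons %||% list()) > 0, "persons")
        inv$studies[[i]]$persons[[1]][[field]] <- NULL
      }
      inv
    },
    "REQ-DF-LINK" = ,
    "REQ-DF-DESCRIPTION" = ,
    "REQ-DF-VERSION" = {
      field <- c("REQ-DF-LINK" = "link", "REQ-DF-DESCRIPTION" = "description",
                 "REQ-DF-VERSION" = "version")[[rule_id]]
      i <- study_with(function(s) length(s$data_files %||% list()) > 0,
                      "data files")
      inv$studies[[i]]$data_files[[1]][[field]] <- NULL
      inv
    },
    "REQ-BM-ID" = {
      i <- study_with(function(s) length(s$biological_materials %||% list()) > 0,
                      "biological materials")
      old <- inv$studies[[i]]$biological_materials[[1]]$id
      inv$studies[[i]]$biological_materials[[1]]$id <- NULL
      inv$studies <- lapply(inv$studies, function(s) {
        s$observation_units <- lapply(s$observation_units %||% list(),
                                      function(o) {
          if (identical(o$biological_material_id, old)) {
            o$biological_material_id <- NULL
          }
          o
        })
        # drop the now-id-less duplicate from sibling studies sharing the list
        s$biological_materials <- Filter(function(b) !identical(b$id, old),
                                         s$biological_materials %||% list())
        s
      })
      inv$studies[[i]]$biological_materials <- c(
        list(miappe_biological_material(
          organism = ontology_ref("Triticum aestivum", "NCBITaxon:4565"))),
        inv$studies[[i]]$biological_materials)
      inv
    },
    "REQ-BM-ORGANISM" = {
      i <- study_with(function(s) length(s$biological_materials %||% list()) > 0,
                      "biological materials")
      inv$studies <- lapply(inv$studies, function(s) {
        # shared materials must stay identical in every study listing them
        target <- inv$studies[[i]]$biological_materials[[1]]$id
        s$biological_materials <- lapply(s$biological_materials %||% list(),
                                         function(b) {
          if (identical(b$id, target)) b$organism <- NULL
          b
        })
        s
      })
      inv
    },
    "REQ-ENV-PARAMETER" = ,
    "REQ-ENV-VALUE" = {
      field <- if (rule_id == "REQ-ENV-PARAMETER") "parameter" else "value"
      i <- study_with(function(s) length(s$environments %||% list()) > 0,
                      "environment parameters")
      inv$studies[[i]]$environments[[1]][[field]] <- NULL
      inv
    },
    "UNIQ-ENV-PARAMETER" = {
      i <- study_with(function(s) length(s$environments %||% list()) >= 2,
                      "two environment parameters")
      inv$studies[[i]]$environments[[2]]$parameter <-
        inv$studies[[i]]$environments[[1]]$parameter
      inv
    },
    "REQ-FAC-TYPE" = ,
    "REQ-FAC-VALUES" = {
      i <- study_with(function(s) length(s$factors %||% list()) > 0, "factors")
      key <- inv$studies[[i]]$factors[[1]]$type$label
      if (rule_id == "REQ-FAC-TYPE") {
        inv$studies[[i]]$factors[[1]]$type <- NULL
      } else {
        inv$studies[[i]]$factors[[1]]$values <- NULL
      }
      inv$studies[[i]]$observation_units <-
        lapply(inv$studies[[i]]$observation_units %||% list(), function(o) {
          o$factor_values[[key]] <- NULL
          if (length(o$factor_values) == 0) o$factor_values <- NULL
          o
        })
      inv
    },
    "UNIQ-FAC-VALUES" = {
      i <- study_with(function(s) length(s$factors %||% list()) > 0, "factors")
      v <- inv$studies[[i]]$factors[[1]]$values
      inv$studies[[i]]$factors[[1]]$values <- c(v, v[1])
      inv
    },
    "REQ-EV-TYPE" = ,
    "REQ-EV-DATE" = {
      field <- if (rule_id == "REQ-EV-TYPE") "type" else "date"
      i <- study_with(function(s) length(s$events %||% list()) > 0, "events")
      inv$studies[[i]]$events[[1]][[field]] <- NULL
      inv
    },
    "REQ-OU-LEVEL" = {
      i <- study_with(function(s) length(s$observation_units %||% list()) > 0,
                      "observation units")
      inv$studies[[i]]$observation_units[[1]]$level <- "warp-zone"
      inv
    },
    "REQ-VAR-ID" = ,
    "REQ-VAR-NAME" = ,
    "REQ-VAR-TRAIT" = ,
    "REQ-VAR-METHOD" = ,
    "REQ-VAR-SCALE" = {
      i <- study_with(function(s) length(s$observed_variables %||% list()) > 0,
                      "observed variables")
      target <- inv$studies[[i]]$observed_variables[[1]]$id
      blank <- function(v) {
        switch(rule_id,
          "REQ-VAR-ID" = { v$id <- NULL },
          "REQ-VAR-NAME" = { v$name <- NULL },
          "REQ-VAR-TRAIT" = { v$trait$name <- NULL },
          "REQ-VAR-METHOD" = { v$method$name <- NULL },
          "REQ-VAR-SCALE" = { v$scale$name <- NULL })
        v
      }
      inv$studies <- lapply(inv$studies, function(s) {
        s$observed_variables <- lapply(s$observed_variables %||% list(),
                                       function(v) {
          if (identical(v$id, target)) v <- blank(v)
          v
        })
        s
      })
      inv
    },
    "REF-SAM-OU" = {
      i <- study_with(function(s) length(s$samples %||% list()) > 0, "samples")
      inv$studies[[i]]$samples[[1]]$observation_unit_id <- "OU-MISSING"
      inv
    },
    "REF-OU-BM" = {
      i <- study_with(function(s) length(s$observation_units %||% list()) > 0,
                      "observation units")
      inv$studies[[i]]$observation_units[[1]]$biological_material_id <-
        "BM-MISSING"
      inv
    },
    "REF-EV-OU" = {
      i <- study_with(function(s) length(s$events %||% list()) > 0, "events")
      inv$studies[[i]]$events[[1]]$affected_units <- "OU-MISSING"
      inv
    },
    "FMT-DATE" = {
      i <- study_with(function(s) length(s$samples %||% list()) > 0, "samples")
      inv$studies[[i]]$samples[[1]]$collection_date <- "2017-06-31"
      inv
    },
    "FMT-DATERANGE" = {
      i <- study_with(function(s) !is_blank(s$start_date), "dated studies")
      inv$studies[[i]]$end_date <- "1900-12-31"
      inv$studies[[i]]$samples <- list()  # avoid out-of-range warnings
      inv
    },
    "FMT-GEO" = {
      i <- study_with(function(s) length(s$locations %||% list()) == 1,
                      "located studies")
      inv$studies[[i]]$locations[[1]]$geo$latitude <- 91
      inv
    },
    "FMT-CURIE" = {
      i <- study_with(function(s) length(s$biological_materials %||% list()) > 0,
                      "biological materials")
      target <- inv$studies[[i]]$biological_materials[[1]]$id
      inv$studies <- lapply(inv$studies, function(s) {
        s$biological_materials <- lapply(s$biological_materials %||% list(),
                                         function(b) {
          if (identical(b$id, target)) b$organism$accession <- "not a curie"
          b
        })
        s
      })
      inv
    },
    "FMT-FACTORVALUE" = {
      i <- study_with(function(s) {
        any(vapply(s$observation_units %||% list(),
                   function(o) length(o$factor_values %||% list()) > 0,
                   logical(1)))
      }, "factor-valued observation units")
      ous <- inv$studies[[i]]$observation_units
      j <- which(vapply(ous, function(o)
        length(o$factor_values %||% list()) > 0, logical(1)))[1]
      key <- names(ous[[j]]$factor_values)[1]
      inv$studies[[i]]$observation_units[[j]]$factor_values[[key]] <-
        "undeclared-value"
      inv
    },
    "WARN-SAM-DATE" = {
      i <- study_with(function(s) length(s$samples %||% list()) > 0 &&
                        !is_blank(s$start_date), "dated samples")
      inv$studies[[i]]$samples[[1]]$collection_date <- "1900-01-01"
      inv
    },
    stop(sprintf("no mutator for rule '%s'", rule_id), call. = FALSE)
  )
  build_dataset(inv, provenance = dataset$provenance)
}
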