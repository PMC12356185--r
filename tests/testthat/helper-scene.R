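# shared desk-scale fixtures, built in code

small_scene <- function(seed = 3, years = c(2020, 2021), w = 40, h = 40,
                        cloud_gap_fraction = 0, noise_sd = 0, ...) {
  scene_config(grid_width = w, grid_height = h, years = years, seed = seed,
               cloud_gap_fraction = cloud_gap_fraction, noise_sd = noise_sd,
               ...)
}

# full forward run: reflectance + climate -> quantized uGPP cube
run_forward <- function(cfg, model = lue_model(), coarse_factor = 8) {
  rc <- gen_reflectance(cfg)
  cl <- gen_climate(cfg, coarse_factor = coarse_factor)
  cal <- bimonthly_calendar(cfg$years[1], cfg$years[2])
  cc <- prepare_climate(cl$lst, cl$lst_dates, cl$par, cl$par_dates,
                        cl$grid, rc$grid, cal)
  list(refl = rc, climate = cc, gpp = predict(model, rc, cc))
}
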