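# scalar STN-GPe pair, density impulse convention, dt=0.1
dt <- 0.1; Tms <- 2000; n <- Tms/dt
mg <- function(v) 1/(1+(1/3.57)*exp(-0.062*v))
run_pair <- function(w_gs = 19.8, w_sg = 0.99, I_stn = 30, I_gpe = 10,
                     g_self_gpe = 0, extra_gaba_stn = 0) {
  vs <- -65; us <- 0.265*vs; vg <- -65; ug <- 0.2*vg
  h_sa <- h_sn <- h_gg <- 0
  ss <- sg <- 0
  st_s <- st_g <- numeric(0)
  for (t in 1:n) {
    h_sa <- h_sa + dt*(-h_sa + ss/dt)/6
    h_sn <- h_sn + dt*(-h_sn + ss/dt)/160
    h_gg <- h_gg + dt*(-h_gg + sg/dt)/4
    Is <- (w_gs + extra_gaba_stn)*h_gg*(-60-vs)
    Ig <- w_sg*(h_sa*(0-vg) + mg(vg)*h_sn*(0-vg)) + g_self_gpe*h_gg*(-60-vg)
    vs2 <- vs + dt*(0.04*vs^2+5*vs-us+140+I_stn+Is)
    us2 <- us + dt*0.005*(0.265*vs-us)
    vg2 <- vg + dt*(0.04*vg^2+5*vg-ug+140+I_gpe+Ig)
    ug2 <- ug + dt*0.1*(0.2*vg-ug)
    ss <- sg <- 0
    if (vs2 >= 30) { vs2 <- -65; us2 <- us2+1.5; ss <- 1; st_s <- c(st_s, t*dt) }
    if (vg2 >= 30) { vg2 <- -65; ug2 <- ug2+2; sg <- 1; st_g <- c(st_g, t*dt) }
    vs <- vs2; us <- us2; vg <- vg2; ug <- ug2
  }
  isi_s <- diff(st_s[st_s > 500])
  cat(sprintf("STN %.0f Hz (ISI cv %.2f, max %.0f ms)  GPe %.0f Hz\n",
      1000*length(st_s[st_s>500])/1500, sd(isi_s)/mean(isi_s), max(isi_s),
      1000*length(st_g[st_g>500])/1500))
}
cat("pair, table-1 weights: "); run_pair()
cat("pair + GPe self-inh 20: "); run_pair(g_self_gpe = 20)
cat("pair, 3x GABA onto STN: "); run_pair(extra_gaba_stn = 40)
cat("pair, GPe driven to high rate (I_gpe=30): "); run_pair(I_gpe = 30)
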