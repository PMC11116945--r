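scale,land_cover,site,abs,coh_p,coh_mean,coh_sd,coh_z,rep,tur_p,tur_mean,tur_sd,tur_z,morisita_i,bnd_p,structure
local,farmland,Heihe,40,0.00,102.21,4.94,-12.58,639,0.08,507.69,75.78,1.73,1.28,0.01,Quasi-Clementsian
local,farmland,Harbin,33,0.00,139.30,5.13,-20.37,1095,0.16,949.87,102.87,1.41,1.11,0.07,Quasi-Gleasonian
local,farmland,Lishu,32,0.00,112.60,5.24,-15.37,764,0.08,627.43,79.09,1.73,1.28,0.01,Quasi-Clementsian
local,farmland,Shenyang,49,0.00,134.78,4.93,-17.39,819,0.05,682.85,70.56,1.93,1.24,0.01,Quasi-Clementsian
local,grassland,Heihe,57,0.00,185.54,6.99,-18.38,1771,0.44,1659.00,145.50,0.77,1.19,0.00,Quasi-Clementsian
local,grassland,Harbin,37,0.00,125.01,4.54,-19.39,1257,0.02,966.69,127.17,2.28,1.21,0.01,Clementsian
local,grassland,Lishu,55,0.00,179.35,6.54,-19.01,1651,0.27,1496.86,141.19,1.09,1.01,0.28,Quasi-Gleasonian
local,grassland,Shenyang,65,0.00,278.34,8.24,-25.89,3184,0.69,3115.31,173.00,0.40,1.50,0.00,Quasi-Clementsian
local,woodland,Heihe,44,0.00,162.95,8.87,-13.41,1463,0.19,1652.90,143.33,-1.32,1.15,0.01,Quasi-nested (clumped loss)
local,woodland,Harbin,38,0.00,159.54,4.21,-28.85,1602,0.00,1241.29,125.16,2.88,1.15,0.02,Clementsian
local,woodland,Lishu,43,0.00,190.65,4.96,-29.77,1800,0.00,1463.85,114.83,2.93,1.07,0.10,Gleasonian
local,woodland,Shenyang,70,0.00,169.00,5.64,-17.55,1247,0.39,1148.96,115.19,0.85,1.29,0.00,Quasi-Clementsian
regional,farmland,NA,666,0.00,1162.01,17.13,-28.96,19264,0.00,13631.22,1772.41,3.18,1.45,0.00,Clementsian
regional,grassland,NA,976,0.00,1784.21,19.08,-42.35,40576,0.00,28797.35,3113.70,3.78,1.71,0.00,Clementsian
regional,woodland,NA,945,0.00,1545.22,19.97,-30.06,30248,0.29,26927.46,3117.31,1.07,1.77,0.00,Quasi-Clementsian
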