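name: wenzhou
units:
  mass: kg
  distance: m
  time: s
  currency: yuan
sets:
  reserve:
  - Shiqu
  - Yongjia
  - Yueqing
  dc:
  - DC1
  - DC2
  area:
  - Rui'an
  - Pingyang
  - Cangnan
  - Wencheng
  - Taishun
  ppe:
  - masks
  - protective_clothing
  vehicle:
  - light
  - medium
  - heavy
parameters:
  coverage: 150000.0
  ppe_weight:
    masks: 0.6
    protective_clothing: 0.4
  vehicle_capacity:
    light: 5000.0
    medium: 10000.0
    heavy: 20000.0
  unit_cost:
    light: 0.1
    medium: 0.2
    heavy: 0.3
  unit_time:
    light: 0.06
    medium: 0.07
    heavy: 0.09
  rent:
    DC1: 800000.0
    DC2: 600000.0
  demand:
    Rui'an:
      masks: 146000.0
      protective_clothing: 0.0
    Pingyang:
      masks: 150000.0
      protective_clothing: 0.0
    Cangnan:
      masks: 165000.0
      protective_clothing: 160.0
    Wencheng:
      masks: 150000.0
      protective_clothing: 11400.0
    Taishun:
      masks: 320000.0
      protective_clothing: 3040.0
  ppe_supply:
    Shiqu:
      masks: 500000.0
      protective_clothing: 6000.0
    Yongjia:
      masks: 150000.0
      protective_clothing: 2000.0
    Yueqing:
      masks: 300000.0
      protective_clothing: 4000.0
  vehicle_supply:
    Shiqu:
      light: 30.0
      medium: 15.0
      heavy: 10.0
    Yongjia:
      light: 10.0
      medium: 5.0
      heavy: 2.0
    Yueqing:
      light: 20.0
      medium: 10.0
      heavy: 5.0
  dc_ppe_cap:
    DC1:
      masks: 800000.0
      protective_clothing: 10000.0
    DC2:
      masks: 600000.0
      protective_clothing: 8000.0
  dc_vehicle_cap:
    DC1:
      light: 50.0
      medium: 25.0
      heavy: 12.0
    DC2:
      light: 40.0
      medium: 20.0
      heavy: 10.0
  distance:
    Shiqu:
      DC1:
        Rui'an: 192994.690605547337327
        Pingyang: 195971.894590493466239
        Cangnan: 153302.586175827833358
        Wencheng: 175200.067467957182089
        Taishun: 125262.13608528158511
      DC2:
        Rui'an: 203341.124671605357435
        Pingyang: 227423.073835712508298
        Cangnan: 242406.377007305127336
        Wencheng: 176265.455968797788955
        Taishun: 215552.174416677444242
    Yongjia:
      DC1:
        Rui'an: 190424.143644849857083
        Pingyang: 193401.347629795985995
        Cangnan: 150732.039215130353114
        Wencheng: 172629.520507259701844
        Taishun: 122691.589124584148522
      DC2:
        Rui'an: 123600.508128776433296
        Pingyang: 147682.457292883598711
        Cangnan: 162665.760464476188645
        Wencheng: 96524.839425968864816
        Taishun: 135811.557873848534655
    Yueqing:
      DC1:
        Rui'an: 157220.181643914052984
        Pingyang: 160197.385628860152792
        Cangnan: 117528.077214194519911
        Wencheng: 139425.558506323897745
        Taishun: 89487.627123648329871
      DC2:
        Rui'an: 191256.082129687943961
        Pingyang: 215338.031293795123929
        Cangnan: 230321.334465387713863
        Wencheng: 164180.413426880375482
        Taishun: 203467.131874760088976
curves:
  masks:
    quad_coeff: 1.366930479692812e-07
    breakpoint: 604800.0
    plateau: 50000.0
  protective_clothing:
    quad_coeff: 1.366930479692812e-07
    breakpoint: 604800.0
    plateau: 50000.0
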