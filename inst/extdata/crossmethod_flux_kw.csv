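plot,date,ray_tracing,hpeval,pyranometer
conifer,June 15,2047.20,2190.43,2130.13
broadleaf,June 15,1653.63,1693.81,1718.01
mixed,June 15,1785.76,1897.00,1791.32
conifer,July 15,2018.65,1936.74,2061.87
broadleaf,July 15,1589.81,1623.74,1445.60
mixed,July 15,1746.10,1884.33,1858.96
conifer,August 15,1926.49,1878.31,1784.59
broadleaf,August 15,1538.54,1478.37,1404.11
mixed,August 15,1704.97,1617.23,1675.78
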