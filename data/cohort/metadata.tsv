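sample_id	patient_id	tissue
P01_R1	P01	tumor
P01_R2	P01	tumor
P01_R3	P01	tumor
P01_R4	P01	tumor
P01_R5	P01	tumor
P02_R1	P02	tumor
P02_R2	P02	tumor
P02_R3	P02	tumor
P02_R4	P02	tumor
P02_R5	P02	tumor
P02_R6	P02	tumor
P02_R7	P02	tumor
P03_R1	P03	tumor
P03_R2	P03	tumor
P03_R3	P03	tumor
P03_R4	P03	tumor
P03_R5	P03	tumor
P03_R6	P03	tumor
P03_R7	P03	tumor
P03_R8	P03	tumor
P03_R9	P03	tumor
P04_R1	P04	tumor
P04_R2	P04	tumor
P04_R3	P04	tumor
P04_R4	P04	tumor
P04_R5	P04	tumor
P04_R6	P04	tumor
P05_R1	P05	tumor
P05_R2	P05	tumor
P05_R3	P05	tumor
P05_R4	P05	tumor
P05_R5	P05	tumor
P05_R6	P05	tumor
P06_R1	P06	tumor
P06_R2	P06	tumor
P06_R3	P06	tumor
P06_R4	P06	tumor
P06_R5	P06	tumor
P06_R6	P06	tumor
P06_R7	P06	tumor
P07_R1	P07	tumor
P07_R2	P07	tumor
P07_R3	P07	tumor
P07_R4	P07	tumor
P07_R5	P07	tumor
P08_R1	P08	tumor
P08_R2	P08	tumor
P08_R3	P08	tumor
P08_R4	P08	tumor
P08_R5	P08	tumor
P08_R6	P08	tumor
P09_R1	P09	tumor
P09_R2	P09	tumor
P09_R3	P09	tumor
P09_R4	P09	tumor
P09_R5	P09	tumor
P09_R6	P09	tumor
P10_R1	P10	tumor
P10_R2	P10	tumor
P10_R3	P10	tumor
P10_R4	P10	tumor
P10_R5	P10	tumor
P10_R6	P10	tumor
P10_R7	P10	tumor
P11_R1	P11	tumor
P11_R2	P11	tumor
P11_R3	P11	tumor
P11_R4	P11	tumor
P11_R5	P11	tumor
P11_R6	P11	tumor
P12_R1	P12	tumor
P12_R2	P12	tumor
P12_R3	P12	tumor
P12_R4	P12	tumor
P12_R5	P12	tumor
P13_R1	P13	tumor
P13_R2	P13	tumor
P13_R3	P13	tumor
P13_R4	P13	tumor
P13_R5	P13	tumor
P13_R6	P13	tumor
P13_R7	P13	tumor
P13_R8	P13	tumor
P13_R9	P13	tumor
P13_R10	P13	tumor
P14_R1	P14	tumor
P14_R2	P14	tumor
P14_R3	P14	tumor
P14_R4	P14	tumor
P14_R5	P14	tumor
P14_R6	P14	tumor
P14_R7	P14	tumor
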